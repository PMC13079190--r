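# ---- evaluation: PCK@50, classification report, screening statistics ----

#' Percentage of correct keypoints at half torso diameter
#'
#' Fraction of joints whose prediction-truth distance is at most (inclusive)
#' half the per-frame torso diameter, the torso diameter being the distance
#' from the left shoulder to the right hip of the ground truth.
#'
#' @param pred,truth `keypoint_sequence` objects with identical frame
#'   counts.
#' @return Fraction in `[0, 1]`.
#' @export
pck_at_50 <- function(pred, truth) {
  if (!identical(dim(pred$coords), dim(truth$coords))) {
    stop("prediction and truth must share joint set and frame count",
         call. = FALSE)
  }
  d <- dim(truth$coords)[3]
  torso <- sqrt(rowSums((truth$coords[, .J$left_shoulder, , drop = FALSE] -
                           truth$coords[, .J$right_hip, , drop = FALSE])^2,
                        dims = 1))
  torso <- as.numeric(torso)
  if (any(torso <= 0)) {
    stop("degenerate geometry: zero torso diameter", call. = FALSE)
  }
  dist2 <- 0
  for (k in seq_len(d)) {
    dist2 <- dist2 + (pred$coords[, , k] - truth$coords[, , k])^2
  }
  # inclusive boundary; the relative epsilon guards float round-off when a
  # distance equals the threshold exactly
  mean(sqrt(dist2) <= 0.5 * torso * (1 + 1e-9))
}

# rank-statistic AUC (equivalent to the Mann-Whitney U normalization)
.auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification report
#'
#' Per-class precision, recall and F1; macro-F1 (unweighted mean over
#' classes present in the truth); one-vs-rest AUC per class from the rank
#' statistic; confusion matrix.  A class absent from `y_true` gets `NA`
#' AUC/recall and is excluded from macro averages with a warning.
#'
#' @param y_true,y_pred Class labels (character or factor).
#' @param y_score Optional score matrix with one column per class (columns
#'   named or in `classes` order) for the AUC.
#' @param classes Class order; defaults to the sorted union of labels.
#' @return Object of class `eval_report`: list with `per_class` data frame,
#'   `macro_f1`, `macro_auc`, `confusion`, `accuracy`.
#' @export
classification_report <- function(y_true, y_pred, y_score = NULL,
                                  classes = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(union(y_true, y_pred))
  conf <- table(factor(y_true, classes), factor(y_pred, classes))
  per <- data.frame(class = classes, support = as.integer(rowSums(conf)),
                    precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                    auc = NA_real_)
  for (i in seq_along(classes)) {
    tp <- conf[i, i]
    fp <- sum(conf[, i]) - tp
    fn <- sum(conf[i, ]) - tp
    per$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    per$recall[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    pr <- per$precision[i]; rc <- per$recall[i]
    per$f1[i] <- if (!is.na(pr) && !is.na(rc) && pr + rc > 0) {
      2 * pr * rc / (pr + rc)
    } else if (per$support[i] > 0) 0 else NA_real_
    if (!is.null(y_score)) {
      sc <- if (!is.null(colnames(y_score))) y_score[, classes[i]] else
        y_score[, i]
      per$auc[i] <- .auc_rank(sc, y_true == classes[i])
    }
  }
  present <- per$support > 0
  if (!all(present)) {
    warning("classes absent from y_true excluded from macro averages: ",
            paste(classes[!present], collapse = ", "), call. = FALSE)
  }
  structure(
    list(per_class = per,
         macro_f1 = mean(per$f1[present]),
         macro_auc = if (is.null(y_score)) NA_real_ else
           mean(per$auc[present], na.rm = TRUE),
         confusion = conf,
         accuracy = sum(diag(conf)) / length(y_true)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Classification report (accuracy ",
      sprintf("%.3f", x$accuracy), ")\n", sep = "")
  pc <- x$per_class
  pc[, 3:6] <- round(pc[, 3:6], 4)
  print(pc, row.names = FALSE)
  cat("macro-F1: ", sprintf("%.4f", x$macro_f1), sep = "")
  if (!is.na(x$macro_auc)) cat("   macro one-vs-rest AUC: ",
                               sprintf("%.4f", x$macro_auc), sep = "")
  cat("\n")
  invisible(x)
}

#' Binary screening statistics for one target class
#'
#' Sensitivity, specificity, positive and negative predictive value of
#' detecting `positive_class` against all others.
#'
#' @param y_true,y_pred Class labels.
#' @param positive_class The screening target (default `"High"`).
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
screening_stats <- function(y_true, y_pred, positive_class = "High") {
  pt <- y_true == positive_class
  pp <- y_pred == positive_class
  tp <- sum(pt & pp); fn <- sum(pt & !pp)
  fp <- sum(!pt & pp); tn <- sum(!pt & !pp)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Evaluate a fitted model on labeled samples
#'
#' Predicts both tasks and assembles the full report: per-class metrics and
#' one-vs-rest AUC for each task, high-risk screening statistics, and
#' optional stratification by stroke type and age group.
#'
#' @param model Fitted `stroke_model`.
#' @param data A `stroke_cohort` or list of `stroke_sample`.
#' @param stratify Add per-stroke-type and per-age-group sub-reports
#'   (default TRUE).
#' @param age_breaks Age bin edges (default 12-14 vs 15-17).
#' @return List with `asym`, `risk` (`eval_report`s), `screening`,
#'   and optionally `by_stroke`, `by_age`.
#' @export
evaluate_model <- function(model, data, stratify = TRUE,
                           age_breaks = c(12, 15, 18)) {
  samples <- if (inherits(data, "stroke_cohort")) data$samples else data
  probs <- predict(model, samples, type = "prob")
  pred <- data.frame(asym = asym_classes()[max.col(probs$asym)],
                     risk = risk_classes()[max.col(probs$risk)])
  y_asym <- vapply(samples, `[[`, "", "label")
  y_risk <- vapply(samples, `[[`, "", "risk")
  out <- list(
    asym = classification_report(y_asym, pred$asym, probs$asym,
                                 classes = asym_classes()),
    risk = classification_report(y_risk, pred$risk, probs$risk,
                                 classes = risk_classes()),
    screening = screening_stats(y_risk, pred$risk, "High")
  )
  if (stratify) {
    st <- vapply(samples, `[[`, "", "stroke_type")
    ages <- vapply(samples, function(s) as.numeric(s$age), numeric(1))
    grp_age <- cut(ages, age_breaks, right = FALSE,
                   labels = paste(utils::head(age_breaks, -1),
                                  utils::tail(age_breaks, -1) - 1,
                                  sep = "-"))
    strat <- function(groups) {
      lapply(split(seq_along(samples), groups), function(idx) {
        if (length(unique(y_asym[idx])) < 2) return(NULL)
        list(asym = classification_report(y_asym[idx], pred$asym[idx],
                                          classes = asym_classes()),
             risk = classification_report(y_risk[idx], pred$risk[idx],
                                          classes = risk_classes()))
      })
    }
    out$by_stroke <- strat(st)
    out$by_age <- strat(grp_age)
  }
  out
}
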