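# ---- augmentation, AdamW, training loop, fitted-model S3 class ----

#' Augment a stroke sample
#'
#' Training-time augmentation on the keypoint stream (horizontal flip with
#' handedness swap, temporal jitter with edge-frame replication, Gaussian
#' coordinate noise) and on the rendered visual stream (crop-scale plus
#' brightness/contrast jitter applied to the grid before encoding).
#' Kinematic features are recomputed from the augmented keypoints, so all
#' modalities stay consistent; labels are preserved (the taxonomy is
#' side-agnostic and the jitters are label-neutral).  Uses the current RNG
#' state: seed the session for reproducibility.
#'
#' @param sample A `stroke_sample`.
#' @param flip_prob Horizontal flip probability (default 0.5).
#' @param max_shift Temporal jitter bound in frames (default 5).
#' @param noise_sd Coordinate noise sd in body units (default 0.01).
#' @param crop_range Crop-scale range (default `c(0.8, 1)`).
#' @param brightness,contrast Photometric jitter half-ranges (default 0.2).
#' @return The augmented `stroke_sample`.
#' @export
augment <- function(sample, flip_prob = 0.5, max_shift = 5L, noise_sd = 0.01,
                    crop_range = c(0.8, 1), brightness = 0.2,
                    contrast = 0.2) {
  s <- sample
  if (stats::runif(1) < flip_prob) {
    s$keypoints <- mirror_keypoints(s$keypoints)
    s$thoracic[, 1] <- -s$thoracic[, 1]
    s$handedness <- if (s$handedness == "right") "left" else "right"
  }
  shift <- sample.int(2L * max_shift + 1L, 1L) - max_shift - 1L
  if (shift != 0L) {
    Tn <- n_frames(s$keypoints)
    idx <- pmin(pmax(seq_len(Tn) - shift, 1L), Tn)
    s$keypoints$coords <- s$keypoints$coords[idx, , , drop = FALSE]
    s$keypoints$conf <- s$keypoints$conf[idx, , drop = FALSE]
    s$thoracic <- s$thoracic[idx, , drop = FALSE]
  }
  if (noise_sd > 0) {
    sd <- noise_sd * s$height
    s$keypoints$coords <- s$keypoints$coords +
      array(stats::rnorm(length(s$keypoints$coords), 0, sd),
            dim(s$keypoints$coords))
  }
  s$kin <- kinematic_features(s$keypoints, thoracic = s$thoracic,
                              body_height = s$height)
  s$rgb <- render_rgb_features(
    s$keypoints, dim = ncol(sample$rgb),
    crop_scale = stats::runif(1, crop_range[1], crop_range[2]),
    brightness = stats::runif(1, -brightness, brightness),
    contrast = 1 + stats::runif(1, -contrast, contrast)
  )
  s
}

#' Training configuration
#'
#' @param epochs Maximum epochs (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param lr AdamW base learning rate (default 1e-4; small synthetic
#'   cohorts train with 1e-3, see the package vignette).
#' @param weight_decay Decoupled weight decay; implements the L2 penalty of
#'   the joint objective once (default 1e-4).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param split Train/validation/test fractions (default 0.7/0.15/0.15).
#' @param augment Apply training-time augmentation (default TRUE).
#' @param gamma,alpha Focal-loss settings for the risk task.
#' @param dropout Overrides the model config dropout when non-`NULL`.
#' @param seed RNG seed for splitting, shuffling, init, dropout and
#'   augmentation.
#' @param validate_fn Optional custom validation metric:
#'   `function(model, val_batch, epoch) -> scalar` (lower is better);
#'   replaces the default validation joint loss for early stopping.
#' @param verbose Print per-epoch progress.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, lr = 1e-4,
                         weight_decay = 1e-4, patience = 10L,
                         split = c(0.7, 0.15, 0.15), augment = TRUE,
                         gamma = 2,
                         alpha = c(Low = 1.0, Medium = 1.5, High = 3.0),
                         dropout = NULL, seed = 1L, validate_fn = NULL,
                         verbose = FALSE) {
  if (abs(sum(split) - 1) > 1e-6) stop("split must sum to 1", call. = FALSE)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay, patience = patience,
                 split = split, augment = augment, gamma = gamma,
                 alpha = alpha, dropout = dropout, seed = seed,
                 validate_fn = validate_fn, verbose = verbose),
            class = "train_config")
}

# AdamW step on a named list of parameter arrays (in place semantics via
# returned state); weight decay only on weight matrices
.adamw_step <- function(P, G, st, lr, wd, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(G)) {
    g <- G[[nm]]
    if (is.null(st$m[[nm]])) {
      st$m[[nm]] <- g * 0
      st$v[[nm]] <- g * 0
    }
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    mh <- st$m[[nm]] / (1 - b1^t)
    vh <- st$v[[nm]] / (1 - b2^t)
    upd <- lr * mh / (sqrt(vh) + eps)
    decay <- if (grepl("_W[0-9]*$|_W$", nm)) lr * wd * P[[nm]] else 0
    P[[nm]] <- P[[nm]] - upd - decay
  }
  list(P = P, st = st)
}

# stratified index split by a label vector
.stratified_split <- function(y, split) {
  n <- length(y)
  sets <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    k <- length(idx)
    n_tr <- round(split[1] * k)
    n_va <- max(1L, round(split[2] * k))
    if (n_tr + n_va > k) n_tr <- k - n_va
    sets$train <- c(sets$train, idx[seq_len(n_tr)])
    sets$val <- c(sets$val, idx[n_tr + seq_len(n_va)])
    rest <- idx[-(seq_len(n_tr + n_va))]
    sets$test <- c(sets$test, rest)
  }
  lapply(sets, sample)
}

.batch_losses <- function(model, batch, tc, training = FALSE) {
  out <- nn_forward(model, batch, training = training)
  p_asym <- softmax(out$asym)
  p_risk <- softmax(out$risk)
  L1 <- cross_entropy_4class(p_asym, batch$y_asym)
  L2 <- focal_loss_3class(p_risk, batch$y_risk, gamma = tc$gamma,
                          alpha = tc$alpha)
  list(out = out, L1 = L1, L2 = L2)
}

#' Fit the multimodal stroke model
#'
#' End-to-end training: per mini-batch, augment, forward, cross-entropy
#' (asymmetry) + focal (risk) losses combined by uncertainty weighting,
#' AdamW updates of network parameters and task log-noise parameters, with
#' early stopping on the validation joint loss (patience epochs without
#' improvement).  The decoupled weight decay implements the L2 term of the
#' joint objective, so it is not added to the loss a second time.
#'
#' @param cohort A `stroke_cohort` (or plain list of `stroke_sample`).
#' @param config A `model_config`.
#' @param control A `train_config`.
#' @return Fitted object of class `stroke_model` with elements `params`,
#'   `log_sigmas`, `bn`, `config`, `scaler`, `history` (per-epoch data
#'   frame), `split` (index sets), `best_epoch`, `control`.
#' @export
fit_stroke_model <- function(cohort, config = model_config(),
                             control = train_config()) {
  samples <- if (inherits(cohort, "stroke_cohort")) cohort$samples else cohort
  tc <- control
  if (!is.null(tc$dropout)) config$dropout <- tc$dropout
  set.seed(tc$seed)
  risk <- vapply(samples, `[[`, "", "risk")
  split <- .stratified_split(risk, tc$split)
  if (!length(split$train) || !length(split$val)) {
    stop("empty train or validation split", call. = FALSE)
  }

  # kinematic feature scaler from the training split
  kin_tr <- do.call(rbind, lapply(samples[split$train], `[[`, "kin"))
  scaler <- list(mean = colMeans(kin_tr),
                 sd = pmax(apply(kin_tr, 2, stats::sd), 1e-6))

  model <- init_model(config, seed = tc$seed)
  model$scaler <- scaler

  # asymmetry-task class weights from the training-split proportions
  # (inverse frequency, normalized to mean 1 over observed classes)
  lab_tr <- vapply(samples[split$train], `[[`, "", "label")
  freq <- table(factor(lab_tr, asym_classes()))
  cw <- ifelse(freq > 0, 1 / pmax(freq, 1), 0)
  cw <- cw / mean(cw[freq > 0])
  class_w <- as.numeric(cw)
  val_batch <- assemble_batch(samples[split$val], scaler)

  opt <- list(m = list(), v = list())
  opt_s <- list(m = c(0, 0), v = c(0, 0))
  step <- 0L
  best <- Inf
  best_state <- NULL
  wait <- 0L
  hist <- list()
  n_tr <- length(split$train)

  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(split$train)
    tl1 <- 0; tl2 <- 0; nb <- 0
    for (start in seq(1, n_tr, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1, n_tr)]
      bs <- samples[idx]
      if (tc$augment) bs <- lapply(bs, augment)
      batch <- assemble_batch(bs, scaler)
      out <- nn_forward(model, batch, training = TRUE)
      ce <- .wce_logit_grad(out$asym, batch$y_asym, class_w)
      L1 <- ce$loss
      fr <- .focal_logit_grad(out$risk, batch$y_risk, tc$gamma,
                              unname(tc$alpha[risk_classes()]))
      L2 <- fr$loss
      w <- task_weights(model$log_sigmas)
      d_asym <- w[1] * ce$grad
      d_risk <- w[2] * fr$grad
      G <- nn_backward(model, out$cache, d_asym, d_risk)
      step <- step + 1L
      upd <- .adamw_step(model$params, G, opt, tc$lr, tc$weight_decay, step)
      model$params <- upd$P
      opt <- upd$st
      # task noise parameters: d(total)/d(log sigma_i) = 1 - L_i / sigma_i^2
      gs <- c(1 - L1 / exp(2 * model$log_sigmas[1]),
              1 - L2 / exp(2 * model$log_sigmas[2]))
      opt_s$m <- 0.9 * opt_s$m + 0.1 * gs
      opt_s$v <- 0.999 * opt_s$v + 0.001 * gs^2
      mh <- opt_s$m / (1 - 0.9^step)
      vh <- opt_s$v / (1 - 0.999^step)
      model$log_sigmas <- model$log_sigmas - tc$lr * mh / (sqrt(vh) + 1e-8)
      tl1 <- tl1 + L1; tl2 <- tl2 + L2; nb <- nb + 1
    }
    vl <- .batch_losses(model, val_batch, tc, training = FALSE)
    w <- task_weights(model$log_sigmas)
    val_total <- joint_loss(vl$L1, vl$L2, model$log_sigmas)
    monitor <- if (is.null(tc$validate_fn)) val_total else
      tc$validate_fn(model, val_batch, epoch)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_asym = tl1 / nb, train_risk = tl2 / nb,
      val_asym = vl$L1, val_risk = vl$L2, val_total = val_total,
      monitor = monitor, w1 = w[1], w2 = w[2],
      sigma1 = exp(model$log_sigmas[1]), sigma2 = exp(model$log_sigmas[2])
    )
    if (tc$verbose) {
      message(sprintf(
        "epoch %3d  train %.4f/%.4f  val %.4f/%.4f  w %.3f/%.3f",
        epoch, tl1 / nb, tl2 / nb, vl$L1, vl$L2, w[1], w[2]))
    }
    if (monitor < best - 1e-8) {
      best <- monitor
      wait <- 0L
      best_state <- list(params = model$params,
                         log_sigmas = model$log_sigmas,
                         bn = as.list(model$bn), epoch = epoch)
    } else {
      wait <- wait + 1L
      if (wait >= tc$patience) break
    }
  }

  if (!is.null(best_state)) {
    model$params <- best_state$params
    model$log_sigmas <- best_state$log_sigmas
    bn <- new.env(parent = emptyenv())
    for (nm in names(best_state$bn)) assign(nm, best_state$bn[[nm]], envir = bn)
    model$bn <- bn
  }
  structure(
    list(params = model$params, log_sigmas = model$log_sigmas,
         bn = model$bn, config = config, scaler = scaler,
         history = do.call(rbind, hist), split = split,
         best_epoch = if (is.null(best_state)) NA_integer_ else
           best_state$epoch,
         stopped_epoch = length(hist), control = tc),
    class = c("stroke_model", "stroke_model_params")
  )
}

#' @export
print.stroke_model <- function(x, ...) {
  cat("Multimodal stroke asymmetry/risk model\n")
  cat("  parameters: ", format(n_parameters(x), big.mark = ","),
      "  modalities: ", paste(x$config$modalities, collapse = "+"),
      "  fusion: ", x$config$fusion, "\n", sep = "")
  cat("  trained ", x$stopped_epoch, " epochs (best epoch ", x$best_epoch,
      "); task weights w1=", round(task_weights(x$log_sigmas)[1], 3),
      ", w2=", round(task_weights(x$log_sigmas)[2], 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.stroke_model <- function(object, ...) {
  h <- object$history
  cat("Training history (", nrow(h), " epochs):\n", sep = "")
  print(utils::tail(h[, c("epoch", "train_asym", "train_risk", "val_asym",
                          "val_risk", "val_total", "w1", "w2")], 5),
        row.names = FALSE)
  cat("\nReceptive field: ", receptive_field(object$config), " frames\n",
      sep = "")
  cat("Sigma (asym, risk): ",
      paste(round(exp(object$log_sigmas), 3), collapse = ", "), "\n",
      sep = "")
  invisible(object)
}

#' Predict asymmetry class and risk level
#'
#' @param object Fitted `stroke_model`.
#' @param newdata A `stroke_cohort` or list of `stroke_sample`.
#' @param type `"class"` for labels, `"prob"` for class probabilities.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return For `type = "class"`: data frame with `asym`, `risk`.  For
#'   `"prob"`: list of two probability matrices `asym`, `risk`.
#' @export
predict.stroke_model <- function(object, newdata, type = c("class", "prob"),
                                 batch_size = 64L, ...) {
  type <- match.arg(type)
  samples <- if (inherits(newdata, "stroke_cohort")) newdata$samples else
    newdata
  n <- length(samples)
  pa <- matrix(0, n, object$config$n_asym)
  pr <- matrix(0, n, object$config$n_risk)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    batch <- assemble_batch(samples[idx], object$scaler)
    out <- nn_forward(object, batch, training = FALSE)
    pa[idx, ] <- softmax(out$asym)
    pr[idx, ] <- softmax(out$risk)
  }
  colnames(pa) <- asym_classes()
  colnames(pr) <- risk_classes()
  if (type == "prob") return(list(asym = pa, risk = pr))
  data.frame(asym = asym_classes()[max.col(pa)],
             risk = risk_classes()[max.col(pr)])
}

#' Plot training history
#'
#' Loss curves and task-weight trajectories of a fitted model.
#'
#' @param x Fitted `stroke_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.stroke_model <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_asym, h$val_asym, h$train_risk,
                                   h$val_risk),
                    type = "l", lty = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("asym train", "asym val", "risk train",
                                 "risk val"),
                   lty = c(1, 2, 1, 2), col = c(1, 1, 2, 2), cex = 0.7)
  graphics::matplot(h$epoch, cbind(h$w1, h$w2), type = "l", lty = 1,
                    col = c(1, 2), xlab = "epoch", ylab = "task weight")
  graphics::legend("topright", c("w1 (asym)", "w2 (risk)"), lty = 1,
                   col = c(1, 2), cex = 0.7)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file archive with a schema version, the config echo, parameter
#' arrays, task noise parameters, normalization state and history.
#'
#' @param model Fitted `stroke_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns the path; `load_checkpoint` the model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(schema = "ttasym-checkpoint/1",
              config = model$config, params = model$params,
              log_sigmas = model$log_sigmas, bn = as.list(model$bn),
              scaler = model$scaler, history = model$history,
              best_epoch = model$best_epoch,
              stopped_epoch = model$stopped_epoch)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "ttasym-checkpoint/1")) {
    stop("unrecognized checkpoint schema", call. = FALSE)
  }
  bn <- new.env(parent = emptyenv())
  for (nm in names(obj$bn)) assign(nm, obj$bn[[nm]], envir = bn)
  structure(
    list(params = obj$params, log_sigmas = obj$log_sigmas, bn = bn,
         config = obj$config, scaler = obj$scaler, history = obj$history,
         best_epoch = obj$best_epoch, stopped_epoch = obj$stopped_epoch),
    class = c("stroke_model", "stroke_model_params")
  )
}
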