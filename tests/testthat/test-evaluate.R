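test_that("PCK@50 counts joints within half the torso diameter, inclusively", {
  s <- fix_sample(params = asymmetry_params(), noise_sd = 0)
  truth <- s$keypoints_clean
  expect_equal(pck_at_50(truth, truth), 1.0)
  # displace exactly half the joints far away
  torso <- sqrt(sum((truth$coords[1, match("left_shoulder", joint_names()), ] -
                       truth$coords[1, match("right_hip", joint_names()), ])^2))
  pred <- truth
  pred$coords[, 1:8, 1] <- pred$coords[, 1:8, 1] + 10 * torso
  expect_equal(pck_at_50(pred, truth), 9 / 17)
  # boundary convention: exactly 0.5 x diameter counts as correct
  tors <- sqrt(rowSums((truth$coords[, match("left_shoulder", joint_names()), ]
                        - truth$coords[, match("right_hip", joint_names()), ])^2))
  pred2 <- truth
  for (j in 1:17) pred2$coords[, j, 1] <- pred2$coords[, j, 1] + 0.5 * tors
  expect_equal(pck_at_50(pred2, truth), 1.0)
  # rigid translation of both leaves the metric unchanged
  shift <- function(kp) { kp$coords <- kp$coords + 3.3; kp }
  expect_equal(pck_at_50(shift(pred), shift(truth)), pck_at_50(pred, truth))
  bad <- truth
  bad$coords[1, match("right_hip", joint_names()), ] <-
    bad$coords[1, match("left_shoulder", joint_names()), ]
  expect_error(pck_at_50(truth, bad), "torso")
})

test_that("classification report matches hand arithmetic on the 2x2 screen", {
  # TP=9 FN=1 FP=2 TN=88
  y_true <- c(rep("High", 10), rep("Low", 90))
  y_pred <- c(rep("High", 9), "Low", rep("High", 2), rep("Low", 88))
  st <- screening_stats(y_true, y_pred, "High")
  expect_equal(unname(st["sensitivity"]), 0.9)
  expect_equal(unname(st["specificity"]), 88 / 90, tolerance = 1e-12)
  expect_equal(round(unname(st["specificity"]), 4), 0.9778)
  r <- classification_report(y_true, y_pred)
  expect_equal(r$per_class$recall[r$per_class$class == "High"], 0.9)
  expect_equal(sum(r$confusion), 100)
  expect_equal(as.numeric(rowSums(r$confusion)),
               as.numeric(table(factor(y_true, r$per_class$class))))
})

test_that("perfect predictions give unit F1 and AUC", {
  y <- rep(c("A", "B", "C"), each = 10)
  sc <- matrix(0, 30, 3, dimnames = list(NULL, c("A", "B", "C")))
  sc[cbind(1:30, match(y, c("A", "B", "C")))] <- 1
  r <- classification_report(y, y, sc)
  expect_true(all(r$per_class$f1 == 1))
  expect_true(all(r$per_class$auc == 1))
  expect_equal(r$macro_f1, 1)
})

test_that("random scores on balanced labels give chance-level AUC", {
  set.seed(31)
  n <- 10000
  y <- sample(c("A", "B"), n, replace = TRUE)
  sc <- cbind(A = stats::runif(n), B = stats::runif(n))
  r <- classification_report(y, sample(y), sc)
  expect_gt(r$per_class$auc[1], 0.47)
  expect_lt(r$per_class$auc[1], 0.53)
})

test_that("rank-statistic AUC and F1 agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (k in 1:100) {
    n <- 60
    y <- sample(c("neg", "pos"), n, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(y)) < 2) next
    sc <- stats::runif(n)
    mine <- ttasym:::.auc_rank(sc, y == "pos")
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = sc, levels = c("neg", "pos"),
      direction = "<"))))
    expect_equal(mine, ref, tolerance = 1e-9)
    yp <- sample(c("neg", "pos"), n, replace = TRUE)
    r <- classification_report(y, yp)
    tp <- sum(y == "pos" & yp == "pos")
    fp <- sum(y == "neg" & yp == "pos")
    fn <- sum(y == "pos" & yp == "neg")
    f1_ref <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(r$per_class$f1[r$per_class$class == "pos"], f1_ref,
                 tolerance = 1e-12)
  }
})

test_that("classes absent from the truth are flagged and excluded from macros", {
  y <- rep("A", 10)
  yp <- c(rep("A", 8), "B", "B")
  sc <- cbind(A = stats::runif(10), B = stats::runif(10))
  expect_warning(r <- classification_report(y, yp, sc,
                                            classes = c("A", "B")),
                 "absent")
  expect_true(is.na(r$per_class$auc[r$per_class$class == "B"]))
  expect_equal(r$macro_f1, r$per_class$f1[r$per_class$class == "A"])
})

test_that("model evaluation produces a coherent stratified report", {
  co <- generate_cohort(cohort_config(n_samples = 50, effect = "strong",
                                      seed = 12))
  m <- fit_stroke_model(co, tiny_config(),
                        train_config(epochs = 2, lr = 1e-3, seed = 3,
                                     batch_size = 25))
  # tiny stratified cells can miss classes; that warning is expected here
  ev <- suppressWarnings(evaluate_model(m, co))
  expect_s3_class(ev$asym, "eval_report")
  expect_true(all(ev$screening[c("sensitivity", "specificity")] >= 0,
                  na.rm = TRUE))
  expect_true(all(names(ev$by_age) %in% c("12-14", "15-17")))
  expect_equal(sum(ev$risk$confusion), 50)
})
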