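# ---- loss stack: cross-entropy, focal, uncertainty-weighted joint loss ----

.EPS_LOG <- 1e-12

.check_simplex <- function(probs, k) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  if (ncol(probs) != k) {
    stop("expected ", k, "-class probability rows", call. = FALSE)
  }
  if (any(probs < 0) || any(probs > 1) ||
      any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("rows must be valid probability simplex points", call. = FALSE)
  }
  probs
}

.label_index <- function(labels, classes) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    idx <- match(labels, classes)
    if (anyNA(idx)) stop("unknown class label", call. = FALSE)
    return(idx)
  }
  as.integer(labels)
}

#' Four-class cross-entropy loss
#'
#' Mean negative log-probability of the true asymmetry class.
#'
#' @param probs `N x 4` matrix of class probabilities (rows on the
#'   simplex), columns ordered as [asym_classes()].
#' @param labels Integer indices, factor, or class names.
#' @return Scalar loss, `>= 0`.
#' @export
cross_entropy_4class <- function(probs, labels) {
  probs <- .check_simplex(probs, 4L)
  idx <- .label_index(labels, asym_classes())
  p <- probs[cbind(seq_len(nrow(probs)), idx)]
  -mean(log(pmax(p, .EPS_LOG)))
}

#' Three-class focal loss for injury risk
#'
#' Cross-entropy modulated by `(1 - p)^gamma` with per-class balance
#' weights, emphasizing the rare high-risk class: loss =
#' `-(1/N) sum alpha_c (1 - p_c)^gamma log(p_c)` over true classes `c`.
#' With `gamma = 0` and unit weights it reduces exactly to cross-entropy.
#'
#' @param probs `N x 3` probability matrix, columns ordered Low, Medium,
#'   High (see [risk_classes()]).
#' @param labels Integer indices, factor, or class names.
#' @param gamma Focusing parameter (default 2).
#' @param alpha Class balance weights, named by risk level; default
#'   3.0 / 1.5 / 1.0 for high / medium / low risk.
#' @return Scalar loss, `>= 0`.
#' @export
focal_loss_3class <- function(probs, labels, gamma = 2,
                              alpha = c(Low = 1.0, Medium = 1.5, High = 3.0)) {
  probs <- .check_simplex(probs, 3L)
  idx <- .label_index(labels, risk_classes())
  if (is.null(names(alpha))) names(alpha) <- risk_classes()
  a <- alpha[risk_classes()][idx]
  p <- pmax(probs[cbind(seq_len(nrow(probs)), idx)], .EPS_LOG)
  mean(-a * (1 - p)^gamma * log(p))
}

#' Task weights from log noise parameters
#'
#' `w_i = 1 / (2 sigma_i^2)` with `sigma_i = exp(log_sigma_i)`.
#'
#' @param log_sigmas Numeric vector of log noise parameters.
#' @return Numeric vector of task weights.
#' @export
task_weights <- function(log_sigmas) 1 / (2 * exp(2 * log_sigmas))

#' Uncertainty-weighted multi-task joint loss
#'
#' `sum_i L_i / (2 sigma_i^2) + sum_i log(sigma_i) + lambda * ||theta||^2`.
#' The log-sigma penalty keeps the learned noise parameters from diverging;
#' the log parametrization keeps `sigma > 0` by construction.
#'
#' @param L_asym,L_injury Task losses.
#' @param log_sigmas Length-2 vector `(log sigma_1, log sigma_2)`.
#' @param params Optional list of parameter arrays for the L2 term.
#' @param lambda L2 regularization strength (default 1e-4).  When training
#'   uses decoupled weight decay the optimizer owns this term and `params`
#'   is left `NULL` here so it is not applied twice.
#' @return Scalar total loss.
#' @export
joint_loss <- function(L_asym, L_injury, log_sigmas = c(0, 0), params = NULL,
                       lambda = 1e-4) {
  w <- task_weights(log_sigmas)
  total <- w[1] * L_asym + w[2] * L_injury + sum(log_sigmas)
  if (!is.null(params) && lambda > 0) {
    total <- total + lambda * sum(vapply(params, function(p) sum(p^2),
                                         numeric(1)))
  }
  total
}

# gradient of mean cross-entropy w.r.t. logits: (softmax - onehot)/N
.ce_logit_grad <- function(logits, idx) {
  p <- softmax(logits)
  n <- nrow(p)
  y <- matrix(0, n, ncol(p))
  y[cbind(seq_len(n), idx)] <- 1
  (p - y) / n
}

# value and logit gradient of the focal loss
.focal_logit_grad <- function(logits, idx, gamma, alpha_vec) {
  p <- softmax(logits)
  n <- nrow(p)
  pt <- pmax(p[cbind(seq_len(n), idx)], .EPS_LOG)
  a <- alpha_vec[idx]
  loss <- mean(-a * (1 - pt)^gamma * log(pt))
  # dL/dp_t for each sample, then chain through softmax
  dpt <- -a * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
  G <- p * (-pt * dpt / n)              # k != t term: dp_t/dz_k = -p_t p_k
  G[cbind(seq_len(n), idx)] <- dpt * pt * (1 - pt) / n
  list(loss = loss, grad = G)
}

# class-weighted CE (training-time variant: weights set from the class
# proportions, as the training algorithm prescribes for the asymmetry task)
.wce_logit_grad <- function(logits, idx, class_w) {
  p <- softmax(logits)
  n <- nrow(p)
  a <- class_w[idx]
  y <- matrix(0, n, ncol(p))
  y[cbind(seq_len(n), idx)] <- 1
  loss <- sum(-a * log(pmax(p[cbind(seq_len(n), idx)], .EPS_LOG))) / sum(a)
  list(loss = loss, grad = a * (p - y) / sum(a))
}
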