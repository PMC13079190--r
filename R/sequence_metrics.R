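# ---- sequence-level biomechanics: per-frame indicators, windowed features,
# ---- rule-based assessment, and 2D -> 3D lifting

.rownorm <- function(M) sqrt(rowSums(M^2))

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# height coordinate under the package conventions (world: y up; image: -y)
.heights <- function(co, mode) if (mode == "world3d") co[, , 2] else -co[, , 2]

.jmat <- function(co, j) co[, j, , drop = FALSE][, 1, ]

#' Estimate stature from a keypoint sequence
#'
#' Median nose-to-lowest-ankle vertical span divided by its anthropometric
#' fraction of stature.  A rough, scale-consistent estimate used when the
#' true body height is not supplied.
#'
#' @param seq A `keypoint_sequence`.
#' @return Estimated body height in the sequence's length unit.
#' @export
estimate_body_height <- function(seq) {
  h <- .heights(seq$coords, seq$mode)
  span <- h[, .J$nose] - pmin(h[, .J$left_ankle], h[, .J$right_ankle])
  stats::median(span) / (.ANTHRO$nose_h - .ANTHRO$ankle_h)
}

#' Per-frame asymmetry indicators
#'
#' Computes the six asymmetry indicators for every frame of a sequence:
#' shoulder rotation difference (deg), normalized shoulder height difference,
#' spinal lateral flexion (signed deg), trunk rotation (deg), hip flexion
#' difference (deg) and pelvic tilt (signed deg).
#'
#' Per-side shoulder rotation is the angle between the upper-arm vector and
#' the torso frontal plane (3D; plane spanned by the torso axis and the
#' shoulder axis) or the torso axis (2D fallback).  Per-side hip flexion is
#' the angle between the thigh vector and the downward torso axis.  Spinal
#' lateral flexion uses the cervical (shoulder midpoint) and lumbar (hip
#' midpoint) proxies plus a thoracic landmark: pass the true thoracic track
#' via `thoracic` when available (e.g. from the synthetic generator);
#' the default proxy is the torso midpoint, under which the indicator
#' reduces to global torso lateral lean.
#'
#' @param seq A `keypoint_sequence`.
#' @param thoracic Optional `T x D` matrix of thoracic landmark positions in
#'   the sequence's coordinate frame.
#' @param body_height Body height in the sequence's unit; estimated with
#'   [estimate_body_height()] when `NULL`.
#' @return `T x 6` matrix with columns `delta_theta_shoulder`,
#'   `delta_h_shoulder`, `alpha_spine`, `trunk_rotation`, `delta_theta_hip`,
#'   `gamma_pelvis`.
#' @export
frame_indicators <- function(seq, thoracic = NULL, body_height = NULL) {
  co <- seq$coords
  mode <- seq$mode
  Tn <- dim(co)[1]
  if (is.null(body_height)) body_height <- estimate_body_height(seq)
  if (body_height <= 0) stop("body_height must be positive", call. = FALSE)

  LS <- .jmat(co, .J$left_shoulder); RS <- .jmat(co, .J$right_shoulder)
  LE <- .jmat(co, .J$left_elbow);    RE <- .jmat(co, .J$right_elbow)
  LH <- .jmat(co, .J$left_hip);      RH <- .jmat(co, .J$right_hip)
  LK <- .jmat(co, .J$left_knee);     RK <- .jmat(co, .J$right_knee)
  mid_sh <- (LS + RS) / 2
  mid_hip <- (LH + RH) / 2
  h <- .heights(co, mode)

  ang_between <- function(u, v) {
    cc <- rowSums(u * v) / (.rownorm(u) * .rownorm(v))
    acos(pmin(1, pmax(-1, cc))) * .deg
  }

  if (mode == "world3d") {
    tax <- mid_sh - mid_hip
    sax <- RS - LS
    n <- .rowcross(tax, sax)
    n <- n / .rownorm(n)
    elev <- function(u) asin(pmin(1, abs(rowSums(u * n)) / .rownorm(u))) * .deg
    th_r <- elev(RE - RS)
    th_l <- elev(LE - LS)
  } else {
    # 2D fallback: angle between upper arm and the downward torso axis
    dax <- mid_hip - mid_sh
    th_r <- ang_between(RE - RS, dax)
    th_l <- ang_between(LE - LS, dax)
  }
  d_sh <- abs(th_r - th_l)

  d_h <- abs(h[, .J$right_shoulder] - h[, .J$left_shoulder]) / body_height

  # spine fit in the (axial = height, lateral = x) frame; the abscissa is
  # anchored at the lumbar landmark so arctan(-b) evaluates the lateral
  # deviation slope at the spine's base rather than extrapolating the
  # parabola to the ground origin (which would amplify landmark noise)
  thor <- if (is.null(thoracic)) (mid_sh + mid_hip) / 2 else thoracic
  lumb_h <- (h[, .J$left_hip] + h[, .J$right_hip]) / 2
  x1 <- (h[, .J$left_shoulder] + h[, .J$right_shoulder]) / 2 - lumb_h
  x3 <- rep(0, Tn)
  x2 <- (if (mode == "world3d") thor[, 2] else -thor[, 2]) - lumb_h
  y1 <- mid_sh[, 1]; y2 <- thor[, 1]; y3 <- mid_hip[, 1]
  if (any(abs(x1 - x2) < 1e-12 | abs(x1 - x3) < 1e-12 | abs(x2 - x3) < 1e-12)) {
    stop("degenerate spine geometry: duplicated axial coordinates",
         call. = FALSE)
  }
  b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) /
    ((x1 - x2) * (x1 - x3) * (x2 - x3))
  alpha <- atan(-b) * .deg

  # trunk rotation: shoulder vs hip axis, transverse plane in 3D
  s_ax <- RS - LS
  h_ax <- RH - LH
  if (mode == "world3d") {
    s2 <- s_ax[, c(1, 3)]
    h2 <- h_ax[, c(1, 3)]
  } else {
    s2 <- s_ax
    h2 <- h_ax
  }
  cc <- abs(rowSums(s2 * h2)) / (.rownorm(s2) * .rownorm(h2))
  trot <- acos(pmin(1, cc)) * .deg

  dax <- mid_hip - mid_sh
  hf_r <- ang_between(RK - RH, dax)
  hf_l <- ang_between(LK - LH, dax)
  d_hip_flex <- abs(hf_r - hf_l)

  dhip <- .rownorm(RH - LH)
  if (any(dhip <= 0)) stop("degenerate geometry: coincident hip joints",
                           call. = FALSE)
  gamma <- atan((h[, .J$right_hip] - h[, .J$left_hip]) / dhip) * .deg

  out <- cbind(d_sh, d_h, alpha, trot, d_hip_flex, gamma)
  colnames(out) <- .IND_NAMES
  out
}

#' Windowed 12-dimensional kinematic features
#'
#' Slides a window (default 5 frames) over the sequence and returns, per
#' window position, the six asymmetry indicators averaged over the window
#' plus their six first temporal derivatives (central difference across the
#' window, per second).
#'
#' @inheritParams frame_indicators
#' @param window Window length in frames (default 5).
#' @return `(T - window + 1) x 12` matrix; mean columns first, then
#'   derivative columns (`d_` prefix).
#' @export
kinematic_features <- function(seq, window = 5, thoracic = NULL,
                               body_height = NULL) {
  Tn <- n_frames(seq)
  if (Tn < window) {
    stop("sequence has ", Tn, " frames; the sliding window needs at least ",
         window, call. = FALSE)
  }
  Fm <- frame_indicators(seq, thoracic = thoracic, body_height = body_height)
  n <- Tn - window + 1L
  cs <- apply(rbind(0, Fm), 2, cumsum)
  means <- (cs[(window + 1):(Tn + 1), , drop = FALSE] -
              cs[1:n, , drop = FALSE]) / window
  dt <- (window - 1) / seq$frame_rate
  derivs <- (Fm[window:Tn, , drop = FALSE] - Fm[1:n, , drop = FALSE]) / dt
  out <- cbind(means, derivs)
  colnames(out) <- c(paste0("mean_", .IND_NAMES), paste0("d_", .IND_NAMES))
  out
}

#' Rule-based assessment of a whole sequence
#'
#' Computes windowed indicators, applies the threshold rules per window, and
#' aggregates: the sequence asymmetry label is the majority vote over window
#' labels (ties broken toward the class with the larger summed
#' threshold-relative excess), and the sequence risk level is the most
#' severe per-window level, since screening cares about the peak loading
#' within the stroke.
#'
#' @inheritParams kinematic_features
#' @param thr Thresholds from [ttasym_thresholds()].
#' @return List with `label`, `risk`, `window_indicators` (window-mean
#'   indicator matrix), `window_labels`, `window_risk`.
#' @export
assess_sequence <- function(seq, thr = ttasym_thresholds(), window = 5,
                            thoracic = NULL, body_height = NULL) {
  kf <- kinematic_features(seq, window = window, thoracic = thoracic,
                           body_height = body_height)
  W <- kf[, 1:6, drop = FALSE]
  colnames(W) <- .IND_NAMES
  n <- nrow(W)
  labels <- character(n)
  risks <- character(n)
  excess <- matrix(0, n, 3, dimnames = list(NULL, c("Shoulder", "Trunk", "Hip")))
  for (i in seq_len(n)) {
    ex <- .segment_excess(W[i, ], thr)
    excess[i, ] <- ex
    labels[i] <- if (all(ex <= 0)) "Normal" else
      c("Shoulder", "Trunk", "Hip")[which.max(ex)]
    k <- sum(ex > 0)
    risks[i] <- if (k == 0) "Low" else if (k == 1) "Medium" else "High"
  }
  tab <- table(factor(labels, levels = asym_classes()))
  top <- names(tab)[tab == max(tab)]
  label <- if (length(top) == 1L) top else {
    # tie: larger total positive excess wins; Normal loses any tie
    cand <- setdiff(top, "Normal")
    if (!length(cand)) "Normal" else {
      tot <- vapply(cand, function(cl) sum(pmax(excess[, cl], 0)), numeric(1))
      cand[which.max(tot)]
    }
  }
  risk <- risk_classes()[max(match(risks, risk_classes()))]
  list(label = label, risk = risk, window_indicators = W,
       window_labels = labels, window_risk = risks,
       kinematic_features = kf)
}

#' Lift a 2D keypoint sequence to 3D
#'
#' Deterministic monocular lifting: torso and head joints are placed on the
#' z = 0 reference plane; each limb joint receives the depth that restores
#' its anthropometric segment length (fraction of `body_height`, anterior
#' solution), followed by temporal smoothing of the depth track.  The 2D
#' projection (x, image y) is preserved exactly.
#'
#' @param seq2d A `keypoint_sequence` in `image2d` mode.
#' @param body_height Body height in the same length unit as the pixel
#'   coordinates.
#' @param smooth Depth smoothing window in frames (default 5).
#' @param conf_floor Confidence below which joints are imputed first
#'   (default 0.3); imputation fails if a joint is missing in over 30% of
#'   frames.
#' @return A `keypoint_sequence` in `world3d` mode whose `(x, -y)` equals the
#'   input `(x, y)`.
#' @export
lift_to_3d <- function(seq2d, body_height, smooth = 5, conf_floor = 0.3) {
  stopifnot(inherits(seq2d, "keypoint_sequence"))
  if (seq2d$mode != "image2d") stop("lift_to_3d expects an image2d sequence",
                                    call. = FALSE)
  if (body_height <= 0) stop("body_height must be positive", call. = FALSE)
  seq2d <- impute_keypoints(seq2d, floor = conf_floor)
  co <- seq2d$coords
  Tn <- dim(co)[1]
  X <- co[, , 1]
  Y <- -co[, , 2]   # world y is up
  Z <- matrix(0, Tn, 17)

  seg <- function(parent, child, ratio) {
    L <- ratio * body_height
    d2 <- sqrt((X[, child] - X[, parent])^2 + (Y[, child] - Y[, parent])^2)
    Z[, child] <<- Z[, parent] + sqrt(pmax(L^2 - d2^2, 0))
  }
  seg(.J$left_shoulder, .J$left_elbow, .ANTHRO$upper_arm)
  seg(.J$left_elbow, .J$left_wrist, .ANTHRO$forearm)
  seg(.J$right_shoulder, .J$right_elbow, .ANTHRO$upper_arm)
  seg(.J$right_elbow, .J$right_wrist, .ANTHRO$forearm)
  seg(.J$left_hip, .J$left_knee, .ANTHRO$thigh)
  seg(.J$left_knee, .J$left_ankle, .ANTHRO$shank)
  seg(.J$right_hip, .J$right_knee, .ANTHRO$thigh)
  seg(.J$right_knee, .J$right_ankle, .ANTHRO$shank)

  if (smooth > 1 && Tn >= smooth) {
    k <- rep(1 / smooth, smooth)
    for (j in 1:17) {
      z <- stats::filter(Z[, j], k, sides = 2)
      Z[, j] <- ifelse(is.na(z), Z[, j], as.numeric(z))
    }
  }
  out <- array(0, c(Tn, 17, 3))
  out[, , 1] <- X
  out[, , 2] <- Y
  out[, , 3] <- Z
  keypoint_sequence(out, seq2d$conf, frame_rate = seq2d$frame_rate,
                    mode = "world3d")
}
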