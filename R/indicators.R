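# ---- asymmetry indicators, thresholds and rule-based labeling ----

.check_finite <- function(...) {
  vals <- c(...)
  if (!all(is.finite(vals))) stop("non-finite input", call. = FALSE)
  invisible(vals)
}

#' Left-right shoulder rotation difference
#'
#' Absolute difference, in degrees, between the right and left shoulder
#' rotation angles; symmetric in its arguments.
#'
#' @param theta_right,theta_left Per-side rotation angles (degrees).
#' @return Non-negative difference in degrees.
#' @export
shoulder_rotation_difference <- function(theta_right, theta_left) {
  .check_finite(theta_right, theta_left)
  abs(theta_right - theta_left)
}

#' Normalized shoulder height difference
#'
#' Absolute vertical difference between the shoulders divided by body height,
#' a dimensionless, scale-invariant indicator.  In image coordinates "height"
#' is measured along the vertical image axis with up = `-y`.
#'
#' @param y_right,y_left Shoulder heights (same length unit as `body_height`).
#' @param body_height Body height; must be positive.
#' @return Dimensionless non-negative value.
#' @export
shoulder_height_difference <- function(y_right, y_left, body_height) {
  .check_finite(y_right, y_left, body_height)
  if (any(body_height <= 0)) stop("body_height must be positive", call. = FALSE)
  abs(y_right - y_left) / body_height
}

#' Spinal lateral flexion from a quadratic spine fit
#'
#' Fits the exact quadratic `y = a x^2 + b x + c` through the cervical,
#' thoracic and lumbar landmarks expressed in the spine frame -- abscissa
#' `x` along the body's vertical reference axis, ordinate `y` the lateral
#' deviation -- and returns the lateral flexion angle
#' `arctan(2 a x_vertex)`, evaluated through the algebraically equivalent
#' `arctan(-b)` which stays defined for a collinear spine (`a = 0`).
#'
#' @param cervical,thoracic,lumbar Numeric length-2 vectors `(axial, lateral)`.
#' @return List with `angle` (signed degrees), the fitted coefficients
#'   `a`, `b`, `c`, and `x_vertex` (`NA` when `a = 0`).
#' @examples
#' spinal_lateral_flexion(c(-1, 1), c(0, 0), c(1, -1))$angle  # 45
#' @export
spinal_lateral_flexion <- function(cervical, thoracic, lumbar) {
  .check_finite(cervical, thoracic, lumbar)
  x <- c(cervical[1], thoracic[1], lumbar[1])
  y <- c(cervical[2], thoracic[2], lumbar[2])
  if (anyDuplicated(x)) {
    stop("degenerate spine geometry: duplicated axial coordinates",
         call. = FALSE)
  }
  co <- .quad_fit(x[1], y[1], x[2], y[2], x[3], y[3])
  ang <- atan(-co["b"]) * .deg
  list(angle = unname(ang), a = unname(co["a"]), b = unname(co["b"]),
       c = unname(co["c"]),
       x_vertex = if (abs(co["a"]) > 0) unname(-co["b"] / (2 * co["a"])) else NA_real_)
}

# exact quadratic through three points (vector-friendly closed form)
.quad_fit <- function(x1, y1, x2, y2, x3, y3) {
  den <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / den
  b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / den
  c <- (x2 * x3 * (x2 - x3) * y1 + x3 * x1 * (x3 - x1) * y2 +
          x1 * x2 * (x1 - x2) * y3) / den
  c(a = a, b = b, c = c)
}

#' Pelvic tilt (obliquity) angle
#'
#' `arctan((h_right - h_left) / d_hip)` in degrees, where `d_hip` is the
#' Euclidean distance between the hip joints.  Sign-preserving: positive when
#' the right hip sits higher; rules use the magnitude.
#'
#' @param h_right,h_left Hip heights.
#' @param hip_right,hip_left Hip joint positions (numeric vectors, any
#'   dimension), used for the inter-hip distance.
#' @return Signed angle in degrees.
#' @export
pelvic_tilt <- function(h_right, h_left, hip_right, hip_left) {
  .check_finite(h_right, h_left, hip_right, hip_left)
  d <- sqrt(sum((hip_right - hip_left)^2))
  if (d <= 0) stop("degenerate geometry: coincident hip joints", call. = FALSE)
  atan((h_right - h_left) / d) * .deg
}

#' Left-right hip flexion difference
#'
#' Absolute difference of the per-side hip flexion angles, degrees.
#'
#' @param theta_right,theta_left Per-side hip flexion angles (degrees).
#' @return Non-negative difference in degrees.
#' @export
hip_flexion_difference <- function(theta_right, theta_left) {
  .check_finite(theta_right, theta_left)
  abs(theta_right - theta_left)
}

#' Trunk rotation angle
#'
#' Unsigned angle between the shoulder axis and the hip axis, projected onto
#' the transverse plane for 3D input (or measured in the image plane for 2D),
#' folded into `[0, 90]` degrees.
#'
#' @param shoulder_line 2 x D matrix: the two shoulder joints (rows).
#' @param hip_line 2 x D matrix: the two hip joints (rows).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
trunk_rotation_angle <- function(shoulder_line, hip_line) {
  s <- shoulder_line[2, ] - shoulder_line[1, ]
  h <- hip_line[2, ] - hip_line[1, ]
  if (length(s) == 3L) {   # transverse plane: drop the vertical (y) component
    s <- s[c(1, 3)]
    h <- h[c(1, 3)]
  }
  ns <- sqrt(sum(s^2)); nh <- sqrt(sum(h^2))
  if (ns == 0 || nh == 0) {
    stop("degenerate geometry: zero-length body axis", call. = FALSE)
  }
  acos(pmin(1, abs(sum(s * h)) / (ns * nh))) * .deg
}

# ---- thresholds ----

#' Clinical asymmetry thresholds
#'
#' Adolescent operating thresholds for the rule-based classifier: shoulder
#' rotation difference 15 deg, normalized shoulder height difference 0.05,
#' spinal lateral flexion 8 deg, hip flexion difference 10 deg, pelvic tilt
#' 5 deg.  `adult_reduction` encodes that adolescent criteria sit 10-15%
#' below adult reference values; [adult_thresholds()] recovers the latter.
#'
#' A forehand-specific 10-20 degree band for the shoulder rotation
#' difference is sometimes quoted in the screening literature without a
#' stated direction (flagging band versus normal band); it is deliberately
#' not wired into the rules here -- construct stroke-specific threshold
#' objects explicitly if such a criterion is wanted.
#'
#' @param shoulder_rot,shoulder_height,spine_flexion,hip_flexion,pelvic_tilt
#'   Positive cutoffs (degrees except `shoulder_height`, dimensionless).
#' @param adult_reduction Fraction in `[0.10, 0.15]` (default 0.125).
#' @return Object of class `ttasym_thresholds`.
#' @export
ttasym_thresholds <- function(shoulder_rot = 15, shoulder_height = 0.05,
                              spine_flexion = 8, hip_flexion = 10,
                              pelvic_tilt = 5, adult_reduction = 0.125) {
  thr <- list(shoulder_rot = shoulder_rot, shoulder_height = shoulder_height,
              spine_flexion = spine_flexion, hip_flexion = hip_flexion,
              pelvic_tilt = pelvic_tilt, adult_reduction = adult_reduction)
  if (any(unlist(thr[1:5]) <= 0)) {
    stop("all thresholds must be strictly positive", call. = FALSE)
  }
  if (adult_reduction < 0.10 || adult_reduction > 0.15) {
    stop("adult_reduction must lie in [0.10, 0.15]", call. = FALSE)
  }
  structure(thr, class = "ttasym_thresholds")
}

#' Adult reference thresholds
#'
#' @param thr Adolescent thresholds from [ttasym_thresholds()].
#' @return A `ttasym_thresholds` object scaled up by `1 / (1 - adult_reduction)`.
#' @export
adult_thresholds <- function(thr = ttasym_thresholds()) {
  f <- 1 / (1 - thr$adult_reduction)
  ttasym_thresholds(thr$shoulder_rot * f, thr$shoulder_height * f,
                    thr$spine_flexion * f, thr$hip_flexion * f,
                    thr$pelvic_tilt * f, thr$adult_reduction)
}

.as_indicators <- function(ind) {
  if (is.list(ind) && !is.data.frame(ind)) ind <- unlist(ind)
  if (is.null(names(ind))) names(ind) <- .IND_NAMES
  miss <- setdiff(.IND_NAMES, names(ind))
  if (length(miss)) stop("missing indicators: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ind[.IND_NAMES]
}

# per-segment threshold-relative excess: (value - threshold) / threshold,
# > 0 means exceedance; shoulder/hip segments take the worse sub-indicator
.segment_excess <- function(ind, thr) {
  ind <- .as_indicators(ind)
  c(
    shoulder = max((ind["delta_theta_shoulder"] - thr$shoulder_rot) / thr$shoulder_rot,
                   (ind["delta_h_shoulder"] - thr$shoulder_height) / thr$shoulder_height),
    trunk = (abs(ind["alpha_spine"]) - thr$spine_flexion) / thr$spine_flexion,
    hip = max((ind["delta_theta_hip"] - thr$hip_flexion) / thr$hip_flexion,
              (abs(ind["gamma_pelvis"]) - thr$pelvic_tilt) / thr$pelvic_tilt)
  )
}

#' Asymmetry class labels
#' @return Character vector of the four asymmetry classes in canonical order.
#' @export
asym_classes <- function() c("Normal", "Shoulder", "Trunk", "Hip")

#' Risk level labels
#' @return Character vector of the three risk levels in canonical order.
#' @export
risk_classes <- function() c("Low", "Medium", "High")

#' Rule-based asymmetry classification
#'
#' Shoulder asymmetry fires when the rotation difference exceeds
#' `thr$shoulder_rot` or the normalized height difference exceeds
#' `thr$shoulder_height`; trunk asymmetry when `|alpha_spine|` exceeds
#' `thr$spine_flexion`; hip asymmetry when the flexion difference exceeds
#' `thr$hip_flexion` or `|gamma_pelvis|` exceeds `thr$pelvic_tilt`
#' (all strict inequalities).  When several segments fire simultaneously the
#' label is the segment with the largest threshold-relative excess
#' `(value - threshold) / threshold`; multi-segment information is carried by
#' the risk level, not this single label.
#'
#' @param ind Named numeric vector with elements `delta_theta_shoulder`,
#'   `delta_h_shoulder`, `alpha_spine`, `trunk_rotation`, `delta_theta_hip`,
#'   `gamma_pelvis` (or an unnamed vector in that order).
#' @param thr Thresholds from [ttasym_thresholds()].
#' @return One of `"Normal"`, `"Shoulder"`, `"Trunk"`, `"Hip"`.
#' @export
classify_asymmetry <- function(ind, thr = ttasym_thresholds()) {
  ex <- .segment_excess(ind, thr)
  if (all(ex <= 0)) return("Normal")
  c(shoulder = "Shoulder", trunk = "Trunk", hip = "Hip")[[which.max(ex)]]
}

#' Rule-based injury-risk level
#'
#' Low risk: no body segment (shoulder, trunk, hip) exceeds its threshold;
#' medium risk: exactly one segment exceeds (isolated involvement); high
#' risk: two or more segments exceed simultaneously (multi-segment kinetic
#' chain involvement).
#'
#' @inheritParams classify_asymmetry
#' @return One of `"Low"`, `"Medium"`, `"High"`.
#' @export
assign_risk_level <- function(ind, thr = ttasym_thresholds()) {
  k <- sum(.segment_excess(ind, thr) > 0)
  if (k == 0) "Low" else if (k == 1) "Medium" else "High"
}

# ---- age normalization ----

#' Age-group normative table
#'
#' Builds an age-norms object from a data frame with columns `indicator`,
#' `age`, `mu`, `sigma` (one row per indicator x single-year age bin,
#' ages 12-17).
#'
#' @param df The normative data frame.
#' @return Object of class `age_norms`.
#' @export
age_norms <- function(df) {
  need <- c("indicator", "age", "mu", "sigma")
  if (!all(need %in% names(df))) {
    stop("age norms need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(table = df), class = "age_norms")
}

#' Default adolescent normative table
#'
#' Normative means and standard deviations per single-year age bin (12-17)
#' for the shoulder rotation difference and spinal lateral flexion
#' indicators, from published adolescent table-tennis cohort statistics.
#' Other indicators have no shipped norms and must be supplied by the user.
#'
#' @return An `age_norms` object.
#' @export
default_age_norms <- function() {
  age_norms(data.frame(
    indicator = rep(c("delta_theta_shoulder", "alpha_spine"), each = 6),
    age = rep(12:17, 2),
    mu = c(11.7, 14.3, 16.1, 14.5, 12.8, 12.1,
           6.5, 8.1, 9.4, 7.7, 6.9, 6.2),
    sigma = c(6.3, 6.9, 7.4, 6.6, 5.8, 5.5,
              3.4, 3.8, 4.3, 3.6, 3.1, 2.9)
  ))
}

#' Age-normalized indicator z-score
#'
#' `(value - mu_age) / sigma_age` using the mean and standard deviation of
#' athletes in the same age group.
#'
#' @param value Raw indicator value.
#' @param age Athlete age in whole years (12-17 for the shipped norms).
#' @param norms An `age_norms` object.
#' @param indicator Indicator name (one of the canonical six).
#' @return Dimensionless z-score.
#' @export
age_normalize <- function(value, age, norms = default_age_norms(),
                          indicator = "delta_theta_shoulder") {
  .check_finite(value)
  tab <- norms$table
  row <- tab[tab$indicator == indicator & tab$age == age, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no age norm for indicator '", indicator, "' at age ", age,
         call. = FALSE)
  }
  if (!is.finite(row$sigma) || row$sigma <= 0) {
    stop("age norm sigma must be positive for indicator '", indicator, "'",
         call. = FALSE)
  }
  (value - row$mu) / row$sigma
}
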