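# ---- synthetic stroke-motion generator ----
#
# Seeded generator of labeled stroke keypoint sequences.  Asymmetries are
# injected additively on joint angles *before* forward kinematics, with the
# injection frames constructed so that the measurement module recovers the
# injected magnitude exactly at the contact instant; ground-truth labels are
# produced by running the rule oracle on the noise-free sequence.

STROKE_TYPES <- c("forehand_drive", "backhand_push", "serve", "chop")

#' Stroke motion template
#'
#' Smooth, bilaterally symmetric parametric joint-angle curves for one stroke
#' type: arm elevation (anterior swing out of the frontal plane), arm
#' abduction, hip flexion and elbow bend, each rising to a peak at the
#' contact instant.  With all asymmetry parameters at zero the generated pose
#' is left-right symmetric in every frame.
#'
#' @param stroke_type One of `"forehand_drive"`, `"backhand_push"`,
#'   `"serve"`, `"chop"`.
#' @param duration Frames per stroke (default 30).
#' @param frame_rate Hz (default 60, so 30 frames span a 0.5 s stroke).
#' @param contact_phase Phase fraction of the contact instant (default 0.7).
#' @return Object of class `stroke_template`.
#' @export
stroke_template <- function(stroke_type = STROKE_TYPES, duration = 30L,
                            frame_rate = 60, contact_phase = 0.7) {
  stroke_type <- match.arg(stroke_type)
  if (contact_phase <= 0 || contact_phase >= 1) {
    stop("contact phase fraction must lie in (0, 1)", call. = FALSE)
  }
  # per-type base/amplitude (degrees) of the symmetric motion component
  p <- switch(stroke_type,
    forehand_drive = list(el = c(12, 40), ab = c(18, 25), hip = c(10, 8), bend = 22),
    backhand_push  = list(el = c(10, 24), ab = c(12, 12), hip = c(8, 6),  bend = 30),
    serve          = list(el = c(15, 55), ab = c(20, 18), hip = c(12, 10), bend = 18),
    chop           = list(el = c(10, 30), ab = c(22, 30), hip = c(14, 9),  bend = 26)
  )
  structure(
    list(stroke_type = stroke_type, duration = as.integer(duration),
         frame_rate = frame_rate, contact_phase = contact_phase,
         contact_frame = max(1L, round(contact_phase * duration)),
         curves = p),
    class = "stroke_template"
  )
}

# raised-cosine bump: 1 on a plateau of +/- `plateau` frames around the
# contact frame, cosine ramp to 0 over `ramp` frames on each side
.contact_bump <- function(t, tc, plateau = 2, ramp = 8) {
  d <- abs(t - tc)
  out <- numeric(length(t))
  out[d <= plateau] <- 1
  sel <- d > plateau & d < plateau + ramp
  out[sel] <- 0.5 * (1 + cos(pi * (d[sel] - plateau) / ramp))
  out
}

#' Asymmetry injection parameters
#'
#' Target magnitudes of the injected asymmetries, in the units of the
#' corresponding indicator (degrees except `shoulder_height`, a fraction of
#' body height).  Each injection is scaled over time by an envelope
#' `sustain + (1 - sustain) * bump(t)` that equals 1 exactly at the contact
#' plateau, so the indicator measured at contact equals the injected target.
#'
#' @param shoulder_rot,shoulder_height,spine_flexion,trunk_rotation,hip_flexion,pelvic_tilt
#'   Non-negative injected magnitudes (signed values allowed for the signed
#'   indicators; magnitudes are what the rules consume).
#' @param sustain Baseline envelope level away from contact, in `[0, 1)`
#'   (default 0.55).
#' @return Object of class `asymmetry_params`.
#' @export
asymmetry_params <- function(shoulder_rot = 0, shoulder_height = 0,
                             spine_flexion = 0, trunk_rotation = 0,
                             hip_flexion = 0, pelvic_tilt = 0,
                             sustain = 0.55) {
  if (sustain < 0 || sustain >= 1) stop("sustain must lie in [0, 1)",
                                        call. = FALSE)
  structure(
    list(shoulder_rot = shoulder_rot, shoulder_height = shoulder_height,
         spine_flexion = spine_flexion, trunk_rotation = trunk_rotation,
         hip_flexion = hip_flexion, pelvic_tilt = pelvic_tilt,
         sustain = sustain),
    class = "asymmetry_params"
  )
}

#' Index of the sliding window centered on the contact instant
#'
#' @param template A `stroke_template`.
#' @param window Sliding-window length (default 5).
#' @return 1-based index into the rows of [kinematic_features()] output.
#' @export
contact_window_index <- function(template, window = 5) {
  template$contact_frame - (window - 1L) %/% 2L
}

# deterministic forward-kinematics pose synthesis (no noise)
.synth_pose <- function(template, params, height) {
  Tn <- template$duration
  tc <- template$contact_frame
  t <- seq_len(Tn)
  bump <- .contact_bump(t, tc)
  env <- params$sustain + (1 - params$sustain) * bump
  cv <- template$curves
  d2r <- pi / 180

  el0 <- (cv$el[1] + cv$el[2] * bump) * d2r
  ab0 <- (cv$ab[1] + cv$ab[2] * bump) * d2r
  psi0 <- (cv$hip[1] + cv$hip[2] * bump) * d2r
  bend <- (cv$bend * bump) * d2r

  el_r <- el0 + params$shoulder_rot * env * d2r
  el_l <- el0
  psi_r <- psi0 + params$hip_flexion * env * d2r
  psi_l <- psi0
  tau <- params$trunk_rotation * env * d2r

  H <- height
  A <- .ANTHRO
  sw <- A$shoulder_halfw * H
  hw <- A$hip_halfw * H
  hip_y <- A$hip_h * H
  sh_y <- A$shoulder_h * H

  co <- array(0, c(Tn, 17, 3))
  set_j <- function(j, x, y, z) {
    co[, j, 1] <<- x; co[, j, 2] <<- y; co[, j, 3] <<- z
  }

  # pelvic tilt: raise/lower the hips symmetrically about the fixed mid-hip
  # point; the offset is solved so arctan(dh / euclidean hip distance)
  # equals the injected angle exactly
  g <- params$pelvic_tilt * env * d2r
  tg <- tan(g)
  dh <- 2 * hw * tg / sqrt(pmax(1 - tg^2, 1e-9))
  set_j(.J$left_hip, rep(hw, Tn), hip_y - dh / 2, rep(0, Tn))
  set_j(.J$right_hip, rep(-hw, Tn), hip_y + dh / 2, rep(0, Tn))

  # shoulders: axis rotated about the vertical by the trunk rotation angle;
  # right shoulder additionally elevated by the height-asymmetry fraction
  ax <- cbind(cos(tau), 0, sin(tau))        # unit left-shoulder direction
  dh_s <- params$shoulder_height * env * H
  ls <- cbind(sw * ax[, 1], sh_y, sw * ax[, 3])
  rs <- cbind(-sw * ax[, 1], sh_y + dh_s, -sw * ax[, 3])
  set_j(.J$left_shoulder, ls[, 1], ls[, 2], ls[, 3])
  set_j(.J$right_shoulder, rs[, 1], rs[, 2], rs[, 3])

  # arms: direction = cos(el) * in-plane component - sin(el) * frontal normal
  n <- cbind(sin(tau), 0, -cos(tau))        # frontal-plane normal
  arm <- function(anchor, side_sign, el) {
    ipd <- cbind(side_sign * sin(ab0) * ax[, 1],
                 -cos(ab0),
                 side_sign * sin(ab0) * ax[, 3])
    u <- cos(el) * ipd - sin(el) * n
    elbow <- anchor + A$upper_arm * H * u
    u2 <- cos(el + bend) * ipd - sin(el + bend) * n
    wrist <- elbow + A$forearm * H * u2
    list(elbow = elbow, wrist = wrist)
  }
  la <- arm(ls, +1, el_l)
  ra <- arm(rs, -1, el_r)
  set_j(.J$left_elbow, la$elbow[, 1], la$elbow[, 2], la$elbow[, 3])
  set_j(.J$left_wrist, la$wrist[, 1], la$wrist[, 2], la$wrist[, 3])
  set_j(.J$right_elbow, ra$elbow[, 1], ra$elbow[, 2], ra$elbow[, 3])
  set_j(.J$right_wrist, ra$wrist[, 1], ra$wrist[, 2], ra$wrist[, 3])

  # legs: thigh rotated anteriorly from the downward torso axis by the hip
  # flexion angle; shank continues at half the flexion
  leg <- function(hipj, psi) {
    hip <- co[, hipj, ]
    dir <- cbind(0, -cos(psi), sin(psi))
    knee <- hip + A$thigh * H * dir
    dir2 <- cbind(0, -cos(psi / 2), sin(psi / 2))
    ankle <- knee + A$shank * H * dir2
    list(knee = knee, ankle = ankle)
  }
  ll <- leg(.J$left_hip, psi_l)
  rl <- leg(.J$right_hip, psi_r)
  set_j(.J$left_knee, ll$knee[, 1], ll$knee[, 2], ll$knee[, 3])
  set_j(.J$left_ankle, ll$ankle[, 1], ll$ankle[, 2], ll$ankle[, 3])
  set_j(.J$right_knee, rl$knee[, 1], rl$knee[, 2], rl$knee[, 3])
  set_j(.J$right_ankle, rl$ankle[, 1], rl$ankle[, 2], rl$ankle[, 3])

  # head: static symmetric placement
  set_j(.J$nose, rep(0, Tn), A$nose_h * H, rep(0.05 * H, Tn))
  set_j(.J$left_eye, rep(A$eye_halfw * H, Tn), A$eye_h * H, rep(0.045 * H, Tn))
  set_j(.J$right_eye, rep(-A$eye_halfw * H, Tn), A$eye_h * H, rep(0.045 * H, Tn))
  set_j(.J$left_ear, rep(A$ear_halfw * H, Tn), A$ear_h * H, rep(0, Tn))
  set_j(.J$right_ear, rep(-A$ear_halfw * H, Tn), A$ear_h * H, rep(0, Tn))

  # thoracic landmark: torso midline plus the lateral offset that makes the
  # quadratic spine fit return the injected flexion angle exactly
  mid_sh_y <- (co[, .J$left_shoulder, 2] + co[, .J$right_shoulder, 2]) / 2
  mid_hip_y <- (co[, .J$left_hip, 2] + co[, .J$right_hip, 2]) / 2
  mid_sh_x <- (co[, .J$left_shoulder, 1] + co[, .J$right_shoulder, 1]) / 2
  mid_hip_x <- (co[, .J$left_hip, 1] + co[, .J$right_hip, 1]) / 2
  mid_sh_z <- (co[, .J$left_shoulder, 3] + co[, .J$right_shoulder, 3]) / 2
  mid_hip_z <- (co[, .J$left_hip, 3] + co[, .J$right_hip, 3]) / 2
  alpha <- params$spine_flexion * env * d2r
  dlat <- -tan(alpha) * (mid_sh_y - mid_hip_y) / 4
  thoracic <- cbind((mid_sh_x + mid_hip_x) / 2 + dlat,
                    (mid_sh_y + mid_hip_y) / 2,
                    (mid_sh_z + mid_hip_z) / 2)
  list(coords = co, thoracic = thoracic)
}

# mean stature (m) by age in years, adolescent reference
.stature_by_age <- function(age) {
  tab <- c(`12` = 1.52, `13` = 1.58, `14` = 1.64, `15` = 1.69,
           `16` = 1.72, `17` = 1.74)
  unname(tab[as.character(pmin(17, pmax(12, round(age))))])
}

#' Generate one labeled synthetic stroke sample
#'
#' Synthesizes a 30-frame `world3d` keypoint sequence from a stroke template
#' with the requested asymmetries injected, attaches ground-truth labels by
#' running the threshold-rule oracle on the noise-free sequence, then adds
#' isotropic Gaussian observation noise and derives the kinematic-feature
#' and rendered-visual-feature modalities from the noisy observation.
#' Deterministic given `seed`.
#'
#' @param template A `stroke_template`.
#' @param params An `asymmetry_params`.
#' @param seed Integer seed.
#' @param age Athlete age in years (12-17).
#' @param handedness `"right"` or `"left"`.
#' @param body_height Stature in meters; drawn around the age-typical value
#'   when `NULL`.
#' @param noise_sd Keypoint jitter standard deviation in normalized body
#'   units (fraction of stature; default 0.01).
#' @param rgb_dim Rendered visual feature dimension (default 256).
#' @return Object of class `stroke_sample`: noisy and clean keypoint
#'   sequences, thoracic track, kinematic features, rendered visual
#'   features, metadata and the oracle labels `label` / `risk`.
#' @export
generate_stroke <- function(template, params = asymmetry_params(), seed = 1L,
                            age = 14L, handedness = "right",
                            body_height = NULL, noise_sd = 0.01,
                            rgb_dim = 256L) {
  stopifnot(inherits(template, "stroke_template"),
            inherits(params, "asymmetry_params"))
  set.seed(seed)
  if (is.null(body_height)) {
    body_height <- .stature_by_age(age) + stats::rnorm(1, 0, 0.05)
  }
  pose <- .synth_pose(template, params, body_height)
  clean <- keypoint_sequence(pose$coords, frame_rate = template$frame_rate,
                             mode = "world3d")
  if (handedness == "left") {
    clean <- mirror_keypoints(clean)
    pose$thoracic[, 1] <- -pose$thoracic[, 1]
  } else if (handedness != "right") {
    stop("unknown handedness: ", handedness, call. = FALSE)
  }
  oracle <- assess_sequence(clean, thoracic = pose$thoracic,
                            body_height = body_height)

  noisy <- clean
  if (noise_sd > 0) {
    s <- noise_sd * body_height
    noisy$coords <- clean$coords +
      array(stats::rnorm(length(clean$coords), 0, s), dim(clean$coords))
    thor <- pose$thoracic + matrix(stats::rnorm(length(pose$thoracic), 0, s),
                                   nrow(pose$thoracic))
  } else {
    thor <- pose$thoracic
  }
  kin <- kinematic_features(noisy, thoracic = thor, body_height = body_height)
  rgb <- render_rgb_features(noisy, dim = rgb_dim)

  structure(
    list(keypoints = noisy, keypoints_clean = clean, thoracic = thor,
         thoracic_clean = pose$thoracic, kin = kin, rgb = rgb,
         stroke_type = template$stroke_type, age = age,
         handedness = handedness, height = body_height,
         label = oracle$label, risk = oracle$risk,
         params = params, template = template, seed = seed),
    class = "stroke_sample"
  )
}

#' @export
print.stroke_sample <- function(x, ...) {
  cat("Synthetic stroke sample: ", x$stroke_type, ", age ", x$age, ", ",
      x$handedness, "-handed, label=", x$label, ", risk=", x$risk, "\n",
      sep = "")
  invisible(x)
}

#' Mirror a stroke sample
#'
#' Applies the horizontal flip consistently across modalities: keypoints and
#' thoracic track mirrored, handedness flipped, kinematic and visual
#' features recomputed from the mirrored observation.  Labels are preserved
#' (the class taxonomy is side-agnostic).
#'
#' @param sample A `stroke_sample`.
#' @return The mirrored `stroke_sample`.
#' @export
mirror_sample <- function(sample) {
  out <- sample
  out$keypoints <- mirror_keypoints(sample$keypoints)
  out$keypoints_clean <- mirror_keypoints(sample$keypoints_clean)
  out$thoracic <- sample$thoracic
  out$thoracic[, 1] <- -out$thoracic[, 1]
  out$thoracic_clean <- sample$thoracic_clean
  out$thoracic_clean[, 1] <- -out$thoracic_clean[, 1]
  out$handedness <- if (sample$handedness == "right") "left" else "right"
  out$kin <- kinematic_features(out$keypoints, thoracic = out$thoracic,
                                body_height = sample$height)
  out$rgb <- render_rgb_features(out$keypoints, dim = ncol(sample$rgb))
  out
}

#' Render per-frame visual features from a stick figure
#'
#' Deterministic low-dimensional stand-in for a learned visual branch: each
#' frame's skeleton is rasterized as a coarse occupancy grid (the 16
#' canonical limb/torso segments sampled onto a `g x g` grid with
#' `g = sqrt(dim)`, body-centered and stature-normalized) and flattened to a
#' `dim`-vector in `[0, 1]`.  The visual modality therefore carries real
#' pose information without pixels or pretrained networks.  Photometric
#' arguments emulate appearance augmentation on the rendered grid.
#'
#' @param x A `stroke_sample` or a `keypoint_sequence`.
#' @param dim Output dimension per frame; must be a perfect square
#'   (default 256).
#' @param crop_scale Zoom factor in (0, 1]; 1 = full view.
#' @param brightness Additive offset applied to the grid.
#' @param contrast Multiplicative factor applied around mid-gray.
#' @return `T x dim` matrix of per-frame features.
#' @export
render_rgb_features <- function(x, dim = 256L, crop_scale = 1,
                                brightness = 0, contrast = 1) {
  seq <- if (inherits(x, "stroke_sample")) x$keypoints else x
  stopifnot(inherits(seq, "keypoint_sequence"))
  g <- as.integer(round(sqrt(dim)))
  if (g * g != dim) stop("dim must be a perfect square", call. = FALSE)
  co <- seq$coords
  Tn <- base::dim(co)[1]
  X <- co[, , 1]
  Yh <- .heights(co, seq$mode)
  # body-centered, stature-normalized view window
  cx <- (X[, .J$left_hip] + X[, .J$right_hip]) / 2
  cy <- (Yh[, .J$left_hip] + Yh[, .J$right_hip]) / 2
  span <- pmax(Yh[, .J$nose] - pmin(Yh[, .J$left_ankle], Yh[, .J$right_ankle]),
               1e-6)
  half <- 0.62 * span / crop_scale
  E <- .base_edges()
  e1 <- match(E[, 1], COCO17)
  e2 <- match(E[, 2], COCO17)
  lam <- (seq_len(8) - 0.5) / 8
  counts <- numeric(Tn * g * g)
  for (l in lam) {
    Px <- (1 - l) * X[, e1, drop = FALSE] + l * X[, e2, drop = FALSE]
    Py <- (1 - l) * Yh[, e1, drop = FALSE] + l * Yh[, e2, drop = FALSE]
    u <- (Px - cx) / (2 * half) + 0.5
    v <- (Py - cy) / (2 * half) + 0.5
    ci <- floor(u * g)
    ri <- floor((1 - v) * g)
    ok <- ci >= 0 & ci < g & ri >= 0 & ri < g
    cell <- (row(ci) - 1L) * (g * g) + ri * g + ci + 1L
    tb <- tabulate(cell[ok], nbins = Tn * g * g)
    counts <- counts + tb
  }
  M <- matrix(pmin(1, counts / 4), Tn, g * g, byrow = TRUE)
  M <- (M - 0.5) * contrast + 0.5 + brightness
  M[] <- pmin(1, pmax(0, M))
  M
}

#' Cohort generation configuration
#'
#' Study-condition defaults: risk proportions 62.8 / 30.5 / 6.7% (low /
#' medium / high), dominant-segment mix among asymmetric samples
#' 27.5 : 21.3 : 13.0 (shoulder : trunk : hip, renormalized), ages uniform
#' over 12-17, 80% right-handed, stroke mix matching the four stroke types'
#' prevalence, keypoint jitter 0.01 body units.
#'
#' Under the deterministic labeling rules a sample is risk-Low exactly when
#' no indicator exceeds its threshold, which is also when its asymmetry
#' label is Normal; the Normal fraction therefore equals the Low fraction
#' and the segment mix is controlled conditionally on being asymmetric.
#'
#' @param n_samples Number of samples.
#' @param risk_props Named or ordered proportions for Low/Medium/High.
#' @param asym_mix Proportions for Shoulder/Trunk/Hip among asymmetric
#'   samples (renormalized internally).
#' @param stroke_props Proportions over the four stroke types.
#' @param ages Integer vector of candidate ages (uniform draw).
#' @param p_right Probability of right-handedness.
#' @param noise_sd Keypoint jitter sd in body units.
#' @param effect `"moderate"` or `"strong"`: label-conditional magnitude
#'   ranges (strong draws exceedances further from the thresholds, giving
#'   wider class separation).
#' @param seed Integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 100L,
                          risk_props = c(Low = 0.628, Medium = 0.305, High = 0.067),
                          asym_mix = c(Shoulder = 0.275, Trunk = 0.213, Hip = 0.130),
                          stroke_props = c(forehand_drive = 0.325,
                                           backhand_push = 0.262,
                                           serve = 0.183, chop = 0.230),
                          ages = 12:17, p_right = 0.8, noise_sd = 0.01,
                          effect = c("moderate", "strong"), seed = 1L) {
  effect <- match.arg(effect)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (any(risk_props < 0) || abs(sum(risk_props) - 1) > 1e-6) {
    stop("risk proportions must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(asym_mix < 0) || sum(asym_mix) <= 0) {
    stop("infeasible asymmetry mix", call. = FALSE)
  }
  if (any(stroke_props < 0) || abs(sum(stroke_props) - 1) > 1e-6) {
    stop("stroke proportions must be non-negative and sum to 1", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), risk_props = risk_props,
         asym_mix = asym_mix / sum(asym_mix), stroke_props = stroke_props,
         ages = ages, p_right = p_right, noise_sd = noise_sd,
         effect = effect, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# label-conditional magnitude factor ranges (x threshold)
.effect_ranges <- function(effect) {
  if (effect == "strong") {
    list(sub = c(0, 0.6), over = c(1.3, 2.0), dom = c(1.5, 2.0))
  } else {
    list(sub = c(0, 0.8), over = c(1.2, 1.8), dom = c(1.35, 1.8))
  }
}

# draw injection parameters realizing one (risk, dominant-segment) target
.draw_params <- function(risk, dominant, thr, effect) {
  rg <- .effect_ranges(effect)
  runifr <- function(r) stats::runif(1, r[1], r[2])
  # sub-threshold baseline for everything
  p <- list(
    shoulder_rot = runifr(rg$sub) * thr$shoulder_rot,
    shoulder_height = runifr(rg$sub) * thr$shoulder_height,
    spine_flexion = runifr(rg$sub) * thr$spine_flexion *
      sample(c(-1, 1), 1),
    trunk_rotation = stats::runif(1, 0, 15),
    hip_flexion = runifr(rg$sub) * thr$hip_flexion,
    pelvic_tilt = runifr(rg$sub) * thr$pelvic_tilt * sample(c(-1, 1), 1)
  )
  if (risk == "Low") {
    return(do.call(asymmetry_params, c(p, list(sustain = 0.55))))
  }
  segments <- dominant
  if (risk == "High") {
    k_extra <- if (stats::runif(1) < 0.75) 1L else 2L
    others <- setdiff(c("Shoulder", "Trunk", "Hip"), dominant)
    segments <- c(dominant, sample(others, k_extra))
  }
  dom_f <- runifr(rg$dom)
  for (sg in segments) {
    f <- if (sg == dominant) dom_f else
      stats::runif(1, rg$over[1], max(rg$over[1] + 0.01, dom_f - 0.05))
    if (sg == "Shoulder") {
      which_sub <- sample(c("rot", "height", "both"), 1,
                          prob = c(0.6, 0.25, 0.15))
      if (which_sub %in% c("rot", "both")) {
        p$shoulder_rot <- f * thr$shoulder_rot
      }
      if (which_sub %in% c("height", "both")) {
        p$shoulder_height <- f * thr$shoulder_height
      }
    } else if (sg == "Trunk") {
      p$spine_flexion <- f * thr$spine_flexion * sample(c(-1, 1), 1)
    } else {
      which_sub <- sample(c("flex", "tilt", "both"), 1,
                          prob = c(0.5, 0.35, 0.15))
      if (which_sub %in% c("flex", "both")) p$hip_flexion <- f * thr$hip_flexion
      if (which_sub %in% c("tilt", "both")) {
        p$pelvic_tilt <- f * thr$pelvic_tilt * sample(c(-1, 1), 1)
      }
    }
  }
  # exceedances are sustained through the stroke so every analysis window
  # registers them (segment involvement is a property of the whole motion)
  do.call(asymmetry_params, c(p, list(sustain = 0.85)))
}

#' Generate a labeled synthetic cohort
#'
#' Draws, per sample, a target risk level and dominant asymmetric segment,
#' synthesizes a stroke realizing that target through label-conditional
#' magnitude ranges (low: all indicators sub-threshold; medium: one segment
#' over; high: two or more segments over, sustained through the stroke),
#' and stores the rule-oracle labels computed from the noise-free motion.
#'
#' @param config A `cohort_config`.
#' @return Object of class `stroke_cohort`: list with `samples` (list of
#'   `stroke_sample`), `manifest` (stratification data frame) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  thr <- ttasym_thresholds()
  set.seed(config$seed)
  n <- config$n_samples
  risk_t <- sample(risk_classes(), n, replace = TRUE, prob = config$risk_props)
  dom_t <- sample(c("Shoulder", "Trunk", "Hip"), n, replace = TRUE,
                  prob = config$asym_mix)
  stroke_t <- sample(names(config$stroke_props), n, replace = TRUE,
                     prob = config$stroke_props)
  age_t <- sample(config$ages, n, replace = TRUE)
  hand_t <- ifelse(stats::runif(n) < config$p_right, "right", "left")
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    params[[i]] <- .draw_params(risk_t[i], dom_t[i], thr, config$effect)
  }
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    samples[[i]] <- generate_stroke(
      stroke_template(stroke_t[i]), params[[i]], seed = seeds[i],
      age = age_t[i], handedness = hand_t[i], noise_sd = config$noise_sd
    )
  }
  manifest <- data.frame(
    id = seq_len(n),
    stroke_type = stroke_t,
    age = age_t,
    handedness = hand_t,
    height = vapply(samples, function(s) s$height, numeric(1)),
    label = vapply(samples, function(s) s$label, character(1)),
    risk = vapply(samples, function(s) s$risk, character(1)),
    seed = seeds
  )
  structure(list(samples = samples, manifest = manifest, config = config),
            class = "stroke_cohort")
}

#' @export
print.stroke_cohort <- function(x, ...) {
  cat("Synthetic stroke cohort: ", nrow(x$manifest), " samples\n", sep = "")
  cat("  asymmetry: ",
      paste(names(table(x$manifest$label)), table(x$manifest$label),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  risk:      ",
      paste(names(table(x$manifest$risk)), table(x$manifest$risk),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
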