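test_that("windowed kinematic features have the documented shape and statics", {
  s <- fix_sample(params = asymmetry_params(), noise_sd = 0)
  kf <- kinematic_features(s$keypoints_clean, thoracic = s$thoracic_clean,
                           body_height = s$height)
  expect_equal(dim(kf), c(30 - 5 + 1, 12))
  # static pose: replicate one frame -> zero derivatives
  co <- s$keypoints_clean$coords
  static <- keypoint_sequence(co[rep(3, 10), , , drop = FALSE],
                              frame_rate = 60)
  kfs <- kinematic_features(static,
                            thoracic = s$thoracic_clean[rep(3, 10), ],
                            body_height = s$height)
  expect_true(all(abs(kfs[, 7:12]) < 1e-10))
  expect_error(kinematic_features(static, window = 11), "window")
})

test_that("a linear indicator ramp yields the ramp slope as derivative feature", {
  # static symmetric pose; the right arm elevation ramps linearly upward,
  # staying above the (constant) left-arm elevation throughout
  s0 <- fix_sample(params = asymmetry_params(), noise_sd = 0)
  Tn <- 30
  fr <- 60
  slope_per_s <- 30   # degrees per second
  co <- s0$keypoints_clean$coords[rep(3, Tn), , , drop = FALSE]
  thor <- s0$thoracic_clean[rep(3, Tn), ]
  jrs <- match("right_shoulder", joint_names())
  jre <- match("right_elbow", joint_names())
  for (t in seq_len(Tn)) {
    ang <- (45 + (t - 1) / fr * slope_per_s) * pi / 180
    rs <- co[t, jrs, ]
    u <- co[t, jre, ] - rs
    L <- sqrt(sum(u^2))
    ip <- u
    ip[3] <- 0
    ip <- ip / sqrt(sum(ip^2))
    co[t, jre, ] <- rs + L * (cos(ang) * ip + sin(ang) * c(0, 0, 1))
  }
  seq <- keypoint_sequence(co, frame_rate = fr)
  kf <- kinematic_features(seq, thoracic = thor, body_height = s0$height)
  d <- kf[, "d_delta_theta_shoulder"]
  expect_equal(stats::median(d), slope_per_s, tolerance = 0.05)
})
test_that("sequence assessment aggregates window rules as documented", {
  s <- fix_sample(params = asymmetry_params(shoulder_rot = 25, sustain = 0.9),
                  noise_sd = 0)
  a <- assess_sequence(s$keypoints_clean, thoracic = s$thoracic_clean,
                       body_height = s$height)
  expect_equal(a$label, "Shoulder")
  expect_equal(a$risk, "Medium")
  expect_true(all(a$window_labels == "Shoulder"))
  # risk takes the most severe window
  expect_equal(risk_classes()[max(match(a$window_risk, risk_classes()))],
               a$risk)
})

test_that("indicators are invariant under uniform rescaling of coordinates", {
  s <- fix_sample(params = asymmetry_params(shoulder_rot = 12,
                                            spine_flexion = 6,
                                            pelvic_tilt = 4), noise_sd = 0)
  f1 <- frame_indicators(s$keypoints_clean, thoracic = s$thoracic_clean,
                         body_height = s$height)
  sc <- s$keypoints_clean
  sc$coords <- sc$coords * 3.7
  f2 <- frame_indicators(sc, thoracic = s$thoracic_clean * 3.7,
                         body_height = s$height * 3.7)
  expect_equal(f2, f1, tolerance = 1e-10)
})

test_that("stature estimation recovers the generated body height", {
  s <- fix_sample(params = asymmetry_params(), noise_sd = 0)
  expect_equal(estimate_body_height(s$keypoints_clean), s$height,
               tolerance = 0.05)
})

test_that("low-confidence joints are interpolated with a missingness cap", {
  s <- fix_sample(params = asymmetry_params(), noise_sd = 0)
  seq <- s$keypoints_clean
  j <- match("left_wrist", joint_names())
  truth <- seq$coords[15, j, ]
  seq$conf[15, j] <- 0.1
  seq$coords[15, j, ] <- 99
  imp <- impute_keypoints(seq)
  expect_equal(imp$coords[15, j, ],
               (seq$coords[14, j, ] + seq$coords[16, j, ]) / 2)
  expect_lt(sqrt(sum((imp$coords[15, j, ] - truth)^2)), 0.05)
  seq$conf[1:15, j] <- 0.1
  expect_error(impute_keypoints(seq), "30%")
})

test_that("2D->3D lifting preserves the projection and anthropometric lengths", {
  s <- fix_sample(params = asymmetry_params(shoulder_rot = 10), noise_sd = 0)
  # project the world sequence to the image plane (pixels, y down)
  H_px <- 400
  co3 <- s$keypoints_clean$coords
  scale <- H_px / s$height
  co2 <- array(0, c(dim(co3)[1], 17, 2))
  co2[, , 1] <- co3[, , 1] * scale
  co2[, , 2] <- -co3[, , 2] * scale
  seq2d <- keypoint_sequence(co2, frame_rate = 60, mode = "image2d")
  lifted <- lift_to_3d(seq2d, body_height = H_px)
  expect_equal(lifted$mode, "world3d")
  # re-projection equals the input exactly
  expect_equal(lifted$coords[, , 1], co2[, , 1])
  expect_equal(-lifted$coords[, , 2], co2[, , 2])
  # forearm length within 5% of the configured ratio
  je <- match("right_elbow", joint_names())
  jw <- match("right_wrist", joint_names())
  seg <- sqrt(rowSums((lifted$coords[, je, ] - lifted$coords[, jw, ])^2))
  expect_true(all(abs(seg / (0.146 * H_px) - 1) < 0.05))
  expect_error(lift_to_3d(s$keypoints_clean, 1.7), "image2d")
})

test_that("a frontal symmetric pose lifts onto the torso reference plane", {
  s <- fix_sample(params = asymmetry_params(), noise_sd = 0)
  co3 <- s$keypoints_clean$coords[1, , ]
  # fabricate a fully frontal static pose: use true limb lengths in 2D
  Tn <- 6
  co2 <- array(NA_real_, c(Tn, 17, 2))
  H_px <- 350
  for (t in seq_len(Tn)) {
    co2[t, , 1] <- co3[, 1] * H_px / s$height
    co2[t, , 2] <- -co3[, 2] * H_px / s$height
  }
  # force limb 2D lengths to equal full anthropometric lengths (arms down)
  seq2d <- keypoint_sequence(co2, frame_rate = 60, mode = "image2d")
  lifted <- lift_to_3d(seq2d, body_height = H_px)
  # torso joints all on the z = 0 plane
  torso <- match(c("left_shoulder", "right_shoulder", "left_hip",
                   "right_hip", "nose"), joint_names())
  expect_true(all(abs(lifted$coords[, torso, 3]) < 1e-9))
})
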