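test_that("generation is deterministic given the seed", {
  tpl <- stroke_template("serve")
  p <- asymmetry_params(shoulder_rot = 18, hip_flexion = 12)
  s1 <- generate_stroke(tpl, p, seed = 99)
  s2 <- generate_stroke(tpl, p, seed = 99)
  expect_identical(s1$keypoints$coords, s2$keypoints$coords)
  expect_identical(s1$rgb, s2$rgb)
  expect_identical(s1$kin, s2$kin)
  s3 <- generate_stroke(tpl, p, seed = 100)
  expect_false(identical(s1$keypoints$coords, s3$keypoints$coords))
})

test_that("zero asymmetry and zero noise give a fully Normal low-risk stroke", {
  for (type in stroke_types) {
    s <- generate_stroke(stroke_template(type), asymmetry_params(),
                         seed = 5, noise_sd = 0)
    a <- assess_sequence(s$keypoints_clean, thoracic = s$thoracic_clean,
                         body_height = s$height)
    expect_true(all(a$window_labels == "Normal"), label = type)
    expect_equal(s$label, "Normal")
    expect_equal(s$risk, "Low")
  }
})

test_that("injected magnitudes are recovered at the contact window", {
  tpl <- stroke_template("forehand_drive")
  iw <- contact_window_index(tpl)
  cases <- list(
    list(arg = "shoulder_rot", col = "mean_delta_theta_shoulder",
         val = 25.8),
    list(arg = "spine_flexion", col = "mean_alpha_spine", val = 10),
    list(arg = "pelvic_tilt", col = "mean_gamma_pelvis", val = 6)
  )
  for (cs in cases) {
    p <- do.call(asymmetry_params, stats::setNames(list(cs$val), cs$arg))
    s <- generate_stroke(tpl, p, seed = 21, noise_sd = 0)
    kf <- kinematic_features(s$keypoints_clean, thoracic = s$thoracic_clean,
                             body_height = s$height)
    expect_equal(unname(kf[iw, cs$col]), cs$val, tolerance = 0.02,
                 label = cs$arg)
  }
})

test_that("measured shoulder asymmetry increases strictly with the injected effect", {
  tpl <- stroke_template("backhand_push")
  iw <- contact_window_index(tpl)
  grid <- c(0, 5, 10, 20, 30)
  measured <- vapply(grid, function(m) {
    s <- generate_stroke(tpl, asymmetry_params(shoulder_rot = m),
                         seed = 33, noise_sd = 0.005)
    kf <- kinematic_features(s$keypoints_clean, thoracic = s$thoracic_clean,
                             body_height = s$height)
    unname(kf[iw, "mean_delta_theta_shoulder"])
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("stored cohort labels agree with the rule oracle at zero noise", {
  co <- generate_cohort(cohort_config(n_samples = 25, noise_sd = 0,
                                      seed = 17))
  for (s in co$samples) {
    a <- assess_sequence(s$keypoints, thoracic = s$thoracic,
                         body_height = s$height)
    expect_equal(a$label, s$label)
    expect_equal(a$risk, s$risk)
  }
})

test_that("cohort risk marginals approximate the configured proportions", {
  co <- generate_cohort(cohort_config(n_samples = 2000, seed = 1,
                                      noise_sd = 0.005))
  frac <- table(factor(co$manifest$risk, risk_classes())) / 2000
  expect_true(frac[["High"]] >= 0.047 && frac[["High"]] <= 0.087)
  expect_equal(unname(frac[["Low"]]), 0.628, tolerance = 0.04)
  expect_equal(unname(frac[["Medium"]]), 0.305, tolerance = 0.08)
  # conditional segment mix among asymmetric samples
  asym <- co$manifest$label[co$manifest$label != "Normal"]
  mix <- table(factor(asym, c("Shoulder", "Trunk", "Hip"))) / length(asym)
  target <- c(0.275, 0.213, 0.130) / sum(c(0.275, 0.213, 0.130))
  expect_equal(unname(as.numeric(mix)), target, tolerance = 0.08)
})

test_that("single-sample cohort and manifest line up", {
  co <- generate_cohort(cohort_config(n_samples = 1, seed = 4))
  expect_length(co$samples, 1)
  expect_equal(nrow(co$manifest), 1)
  expect_equal(co$manifest$label, co$samples[[1]]$label)
})

test_that("infeasible cohort configurations are rejected", {
  expect_error(cohort_config(n_samples = 0), "n_samples")
  expect_error(cohort_config(risk_props = c(0.5, 0.4, 0.3)), "sum to 1")
  expect_error(cohort_config(asym_mix = c(-1, 1, 1)), "infeasible")
})

test_that("rendered visual features are deterministic pose encodings", {
  s <- fix_sample()
  r1 <- render_rgb_features(s)
  expect_equal(dim(r1), c(30, 256))
  expect_true(all(r1 >= 0 & r1 <= 1))
  expect_identical(r1, render_rgb_features(s))
  # identical poses give identical features
  expect_identical(r1[1, ], render_rgb_features(s)[1, ])
  # mirrored sample: features equal those recomputed from the mirrored pose
  m <- mirror_sample(s)
  expect_identical(m$rgb, render_rgb_features(m$keypoints))
  sm <- s$keypoints
  sm$coords[, , 1] <- -sm$coords[, , 1]   # label swap does not move geometry
  expect_equal(render_rgb_features(sm),
               render_rgb_features(mirror_keypoints(s$keypoints)),
               tolerance = 1e-12)
})

test_that("mirroring a sample preserves indicator magnitudes and labels", {
  s <- fix_sample(params = asymmetry_params(shoulder_rot = 22,
                                            spine_flexion = -9,
                                            pelvic_tilt = 6))
  m <- mirror_sample(s)
  f1 <- frame_indicators(s$keypoints_clean, thoracic = s$thoracic_clean,
                         body_height = s$height)
  f2 <- frame_indicators(m$keypoints_clean, thoracic = m$thoracic_clean,
                         body_height = s$height)
  expect_equal(abs(f2), abs(f1), tolerance = 1e-9)
  expect_equal(m$label, s$label)
  expect_equal(m$risk, s$risk)
  expect_equal(m$handedness, "left")
})
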