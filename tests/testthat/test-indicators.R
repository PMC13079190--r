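test_that("shoulder rotation difference is a symmetric absolute difference", {
  expect_equal(shoulder_rotation_difference(50.0, 31.7), 18.3)
  expect_equal(shoulder_rotation_difference(42, 42), 0)
  expect_equal(shoulder_rotation_difference(10, 30), 20)
  expect_equal(shoulder_rotation_difference(30, 10), 20)
  expect_error(shoulder_rotation_difference(NaN, 1), "finite")
})

test_that("shoulder height difference is height-normalized and scale invariant", {
  expect_equal(shoulder_height_difference(1.4, 1.4, 1.7), 0)
  expect_equal(shoulder_height_difference(0.06 * 1.7, 0, 1.7), 0.06)
  c0 <- shoulder_height_difference(1.45, 1.38, 1.68)
  expect_equal(shoulder_height_difference(1.45 * 3.2, 1.38 * 3.2, 1.68 * 3.2),
               c0)
  expect_error(shoulder_height_difference(1, 2, 0), "positive")
})

test_that("spinal lateral flexion matches closed-form interpolation", {
  # horizontal line: no flexion
  r <- spinal_lateral_flexion(c(-1, 2), c(0, 2), c(1, 2))
  expect_equal(r$angle, 0)
  expect_equal(r$b, 0)
  # collinear slope -1: a = 0 stays defined, angle 45 deg
  r <- spinal_lateral_flexion(c(-1, 1), c(0, 0), c(1, -1))
  expect_equal(r$angle, 45)
  expect_equal(r$a, 0)
  expect_equal(r$b, -1)
  # symmetric parabola: vertex at 0 -> 0 deg
  r <- spinal_lateral_flexion(c(-1, 0), c(0, 1), c(1, 0))
  expect_equal(r$angle, 0)
  expect_equal(r$a, -1)
  expect_equal(r$x_vertex, 0)
  expect_error(spinal_lateral_flexion(c(0, 1), c(0, 2), c(1, 0)),
               "degenerate")
})

test_that("vertex-slope identity arctan(2 a x_vertex) == arctan(-b) holds over random triples", {
  set.seed(42)
  for (i in 1:10000) {
    x <- sort(stats::rnorm(3, sd = 2))
    if (min(diff(x)) < 1e-6) next
    y <- stats::rnorm(3, sd = 2)
    r <- spinal_lateral_flexion(c(x[1], y[1]), c(x[2], y[2]), c(x[3], y[3]))
    if (abs(r$a) > 1e-12) {
      expect_equal(atan(2 * r$a * r$x_vertex), atan(-r$b), tolerance = 1e-10)
    }
  }
})

test_that("pelvic tilt is the arctangent of height difference over hip distance", {
  hr <- c(0.1, 0.53, 0); hl <- c(-0.1, 0.53, 0)
  expect_equal(pelvic_tilt(0.53, 0.53, hr, hl), 0)
  d <- sqrt(sum((hr - hl)^2))
  expect_equal(pelvic_tilt(0.53 + d, 0.53, hr, hl), 45)
  expect_equal(pelvic_tilt(0.53 + 0.0875 * d, 0.53, hr, hl), 5,
               tolerance = 0.01)
  expect_lt(pelvic_tilt(0.53, 0.54, hr, hl), 0)  # sign-preserving
  expect_error(pelvic_tilt(1, 1, hr, hr), "degenerate")
})

test_that("hip flexion difference behaves like the shoulder difference", {
  expect_equal(hip_flexion_difference(95, 95), 0)
  expect_equal(hip_flexion_difference(100, 89), 11)
  expect_equal(hip_flexion_difference(89, 100), 11)
})

test_that("trunk rotation is the folded angle between body axes", {
  sh <- rbind(c(-0.2, 0, 0), c(0.2, 0, 0))
  hp <- rbind(c(-0.1, -0.3, 0), c(0.1, -0.3, 0))
  expect_equal(trunk_rotation_angle(sh, hp), 0)
  rot <- function(deg) {
    a <- deg * pi / 180
    cbind(c(cos(a), 0, -sin(a)), c(0, 1, 0), c(sin(a), 0, cos(a)))
  }
  for (deg in c(30, 60, 90)) {
    shr <- sh %*% t(rot(deg))
    expect_equal(trunk_rotation_angle(shr, hp), deg, tolerance = 1e-10)
  }
  # folded: 120 deg rotation reads as 60
  expect_equal(trunk_rotation_angle(sh %*% t(rot(120)), hp), 60,
               tolerance = 1e-10)
  expect_error(trunk_rotation_angle(rbind(sh[1, ], sh[1, ]), hp),
               "degenerate")
})

test_that("rule-based asymmetry classification fires at the documented thresholds", {
  base <- c(delta_theta_shoulder = 0, delta_h_shoulder = 0, alpha_spine = 0,
            trunk_rotation = 0, delta_theta_hip = 0, gamma_pelvis = 0)
  expect_equal(classify_asymmetry(base), "Normal")
  i <- base; i["delta_theta_shoulder"] <- 16
  expect_equal(classify_asymmetry(i), "Shoulder")
  i <- base; i["alpha_spine"] <- 14.8
  expect_equal(classify_asymmetry(i), "Trunk")
  i <- base; i["alpha_spine"] <- -14.8       # magnitude rule
  expect_equal(classify_asymmetry(i), "Trunk")
  i <- base; i["delta_h_shoulder"] <- 0.06
  expect_equal(classify_asymmetry(i), "Shoulder")
  i <- base; i["gamma_pelvis"] <- -5.5
  expect_equal(classify_asymmetry(i), "Hip")
  # tie-break: largest threshold-relative excess wins
  i <- base; i["delta_theta_shoulder"] <- 16.5   # excess 0.10
  i["delta_theta_hip"] <- 13                      # excess 0.30
  expect_equal(classify_asymmetry(i), "Hip")
})

test_that("risk level counts simultaneously exceeding segments and is monotone", {
  base <- c(delta_theta_shoulder = 0, delta_h_shoulder = 0, alpha_spine = 0,
            trunk_rotation = 0, delta_theta_hip = 0, gamma_pelvis = 0)
  expect_equal(assign_risk_level(base), "Low")
  i <- base; i["delta_theta_shoulder"] <- 20
  expect_equal(assign_risk_level(i), "Medium")
  i["alpha_spine"] <- 10.5
  expect_equal(assign_risk_level(i), "High")
  i["delta_theta_hip"] <- 12
  expect_equal(assign_risk_level(i), "High")
  # adding an exceeding segment never lowers the level
  lv <- function(x) match(assign_risk_level(x), risk_classes())
  set.seed(7)
  for (k in 1:50) {
    i <- base
    i["delta_theta_shoulder"] <- stats::runif(1, 0, 30)
    i["alpha_spine"] <- stats::runif(1, 0, 16)
    l0 <- lv(i)
    i["delta_theta_hip"] <- 11
    expect_gte(lv(i), l0)
  }
})

test_that("adult thresholds sit 10-15% above the adolescent defaults", {
  thr <- ttasym_thresholds()
  ad <- adult_thresholds(thr)
  expect_equal(ad$shoulder_rot, 15 / (1 - 0.125))
  expect_gt(ad$pelvic_tilt, thr$pelvic_tilt)
  expect_error(ttasym_thresholds(adult_reduction = 0.3), "0.10")
  expect_error(ttasym_thresholds(shoulder_rot = -1), "positive")
})

test_that("age normalization is the group z-score with a sigma guard", {
  norms <- age_norms(data.frame(indicator = "delta_theta_shoulder",
                                age = 14, mu = 16.1, sigma = 7.4))
  expect_equal(age_normalize(16.1, 14, norms), 0)
  expect_equal(age_normalize(16.1 + 7.4, 14, norms), 1)
  bad <- age_norms(data.frame(indicator = "delta_theta_shoulder",
                              age = 14, mu = 16.1, sigma = 0))
  expect_error(age_normalize(10, 14, bad), "positive")
  expect_error(age_normalize(10, 30, norms), "no age norm")
  # shipped defaults cover both normed indicators over ages 12-17
  expect_equal(age_normalize(11.7, 12, default_age_norms()), 0)
  expect_equal(age_normalize(6.2 + 2.9, 17, default_age_norms(),
                             indicator = "alpha_spine"), 1)
})
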