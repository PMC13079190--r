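# shared constants; this file collates first

.deg <- 180 / pi

# Canonical 17-joint dictionary (COCO ordering), used by every module.
COCO17 <- c(
  "nose", "left_eye", "right_eye", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)

.J <- as.list(stats::setNames(1:17, COCO17))

.IND_NAMES <- c("delta_theta_shoulder", "delta_h_shoulder", "alpha_spine",
                "trunk_rotation", "delta_theta_hip", "gamma_pelvis")

# anthropometric segment proportions (fractions of body height), adolescent
# reference values shared by the generator, the 2D->3D lifter and the
# stature estimator so measurements and synthesis stay consistent
.ANTHRO <- list(
  nose_h = 0.930, eye_h = 0.940, ear_h = 0.935,
  eye_halfw = 0.033, ear_halfw = 0.060,
  shoulder_h = 0.818, hip_h = 0.530, knee_h = 0.285, ankle_h = 0.039,
  shoulder_halfw = 0.115, hip_halfw = 0.0655,
  upper_arm = 0.186, forearm = 0.146,
  thigh = 0.245, shank = 0.246
)
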