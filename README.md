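# ttasym

Posture-asymmetry recognition and biomechanical injury-risk screening for
table-tennis stroke motion.

Adolescent racquet-sport athletes load one side of the body repetitively
while the skeleton is still maturing; sustained left-right asymmetries of
the shoulder girdle, spine and pelvis are treated in pediatric sports
medicine as precursors of overuse injury.  `ttasym` turns 17-keypoint pose
sequences of individual strokes into (a) six quantitative asymmetry
indicators with clinical threshold rules and (b) learned predictions of the
asymmetry pattern and a three-level biomechanical risk stratum.  Risk here
is a screening stratification of postural loading, not a forecast of injury
incidence.

## What is inside

**Indicators and rules.** Per frame: shoulder rotation difference
`Δθ = |θ_R − θ_L|`, normalized shoulder height difference
`Δh = |y_R − y_L| / H_body`, spinal lateral flexion
`α = arctan(2a·x_vertex) = arctan(−b)` from an exact quadratic fit through
cervical/thoracic/lumbar landmarks, trunk rotation, hip flexion difference,
and pelvic tilt `γ = arctan(Δh_hip / d_hip)`.  Adolescent thresholds
(15°, 0.05, 8°, 10°, 5°, strict) classify each 5-frame window; zero / one /
multiple simultaneously exceeding body segments map to low / medium / high
risk.  Age-bin z-score normalization (`(θ − μ_age)/σ_age`) is included.

**Synthetic stroke generator.** Seeded forward-kinematic templates for four
stroke types with additive joint-angle asymmetry injections that peak at
the contact instant and are *exactly* recoverable by the measurement module
— the contract that makes the whole pipeline testable without restricted
video data.  Cohort sampling reproduces the study's risk marginal
(62.8 / 30.5 / 6.7 %) with label-conditional magnitudes.

**Network.** A sport-weighted skeleton graph (racket-arm chain ×1.5,
cross-lateral edges ×1.3) feeding `D̃^(−1/2) Ã D̃^(−1/2) H W` graph
convolutions; a 4-layer causal dilated temporal convolution stack
(kernel 5, dilations 1,2,4,8, receptive field 61 frames); cross-modal
attention `A = softmax(Q K′/√d_k)` fusing skeleton, kinematic and rendered
visual features into a 512-d representation; dual task heads
(256-128-64-{4,3}).  Trained with cross-entropy + focal loss
(γ = 2, α = 3.0/1.5/1.0 for high/medium/low) under homoscedastic
uncertainty weighting `w_i = 1/(2σ_i²) + Σ log σ_i`, AdamW, augmentation,
and early stopping (patience 10).  Forward, backward and the optimizer are
implemented on plain BLAS products and verified against finite differences.

## Worked example

```r
library(ttasym)

# one synthetic forehand with a 25.8 degree shoulder-rotation asymmetry
tpl <- stroke_template("forehand_drive")
s <- generate_stroke(tpl, asymmetry_params(shoulder_rot = 25.8),
                     seed = 7, noise_sd = 0)
kf <- kinematic_features(s$keypoints_clean, thoracic = s$thoracic_clean,
                         body_height = s$height)
round(kf[contact_window_index(tpl), 1:6], 2)
#> mean_delta_theta_shoulder     mean_delta_h_shoulder      mean_alpha_spine
#>                     25.80                      0.00                  0.00
#>       mean_trunk_rotation      mean_delta_theta_hip     mean_gamma_pelvis
#>                      0.00                      0.00                  0.00
s$label; s$risk
#> [1] "Shoulder"
#> [1] "Medium"
```

The injected 25.8° is recovered exactly at the contact window; a single
exceeding segment yields the medium-risk stratum.  Fitting the classifier
on a cohort:

```r
co <- generate_cohort(cohort_config(n_samples = 600, effect = "strong",
                                    noise_sd = 0.005, seed = 42))
m <- fit_stroke_model(co, model_config(dropout = 0.2),
                      train_config(epochs = 30, lr = 1e-3, seed = 7))
ev <- evaluate_model(m, co$samples[m$split$val])
ev$asym$macro_f1   # validation macro-F1, asymmetry (four classes)
ev$risk$macro_auc  # validation one-vs-rest AUC, risk (three levels)
```

Both validation scores exceed 0.90 under this strong-effect desk-scale
cohort (internal-consistency gates, not reproductions of published
real-data figures; see the methods vignette).

A command-line wrapper ships in `inst/cli/ttasym` with subcommands
`simulate | assess | train | evaluate | report`.

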