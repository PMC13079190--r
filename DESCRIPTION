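Package: ttasym
Title: Posture Asymmetry Recognition and Injury Risk Screening for Table
    Tennis Strokes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies postural asymmetry in adolescent table-tennis stroke
    motion from 17-keypoint pose sequences and stratifies biomechanical injury
    risk.  Implements a six-indicator asymmetry system (shoulder rotation and
    height differences, spinal lateral flexion from a quadratic spine fit,
    trunk rotation, hip flexion difference, pelvic tilt) with adolescent
    clinical thresholds and rule-based low/medium/high risk assignment; a
    sport-weighted skeleton graph convolutional network combined with a causal
    dilated temporal convolutional network and cross-modal attention fusion of
    skeleton, kinematic and rendered visual features; focal and
    uncertainty-weighted multi-task losses trained with AdamW and early
    stopping; a seeded synthetic stroke-motion generator with controllable
    injected asymmetries; and evaluation utilities (PCK@50, per-class
    precision/recall/F1, one-vs-rest AUC, screening sensitivity/specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
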