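Package: squatstab
Title: Knee Instability Classification from Multimodal Squat Exergame Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting dynamic knee instability during
    repeated squats recorded with a depth camera (knee and torso positions) and
    a force plate (center-of-pressure trajectory). Provides a synthetic cohort
    generator with per-squat ground truth, dual-rate stream synchronization by
    linear interpolation, zero-phase Butterworth low-pass filtering, squat-cycle
    segmentation with spurious-detection rejection, five biomechanical features
    (knee shakiness, knee distance, squat depth, sway velocity, sway area),
    threshold-based instability labeling, Spearman rho and phi correlation
    feature ranking, an LSTM sequence classifier and an RBF-kernel SVM, and
    precision/recall/F1/accuracy/ROC-AUC evaluation across feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
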