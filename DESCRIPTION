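Package: oxtrace
Title: Regressor-Based Calcium Imaging, pERK and Tail-Bout Analysis with
    Synthetic Ground Truth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for pulsed-chemosensory calcium imaging
    experiments in larval zebrafish: delta-f-over-f computation, zero-phase
    smoothing, dye-drift background subtraction, GCaMP6s kernel-convolved
    stimulus and motor regressors, threshold-based suppressed/enhanced
    response classification, K-means clustering of neuron-by-regressor
    correlation matrices with BIC/AIC model-order diagnostics, normalized
    pERK activity quantification with a control-calibrated active-cell
    statistic, and tail-bout kinematics.  A synthetic-data generator plants
    known tuning classes and modulation labels so every stage of the
    pipeline can be verified against ground truth without access to raw
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
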