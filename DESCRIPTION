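Package: edgeBP
Title: Quantization-Robust 1D CNN Benchmarking for Cuffless Blood Pressure
    Estimation from PPG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, microcontroller-oriented evaluation framework for
    cuffless blood pressure estimation from single-channel photoplethysmography
    (PPG). Provides a synthetic paired PPG/arterial-pressure cohort generator
    with per-beat ground truth, the standard conditioning pipeline (record
    filtering, detrending, min-max normalization, overlapping 1024-sample
    windowing with systolic/diastolic labeling, split and deduplication
    protocol), five compact 1D convolutional architecture families with an
    in-package gradient training engine (Huber or MSE loss, Adam/AdamW,
    plateau scheduling, early stopping), a self-contained full-integer INT8
    post-training quantization engine with fixed-point requantization and an
    integer-only executor, and an evaluation suite covering ME/SD/MAE error
    statistics, AAMI-style reference thresholds, FP32-INT8 consistency and
    quantization-drift analysis, and deployment feasibility arithmetic
    (weight/activation footprints, duty cycle).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
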