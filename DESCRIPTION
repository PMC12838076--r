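Package: ppglucose
Title: Blood Glucose Estimation from Photoplethysmography Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for non-invasive blood glucose estimation from
    photoplethysmography (PPG) waveforms. Provides synthetic PPG generation
    with controllable artifacts, WFDB-compatible waveform input/output,
    glucose-aligned window extraction, missing-value repair, zero-phase
    Butterworth bandpass filtering, systolic peak and valley detection with
    step-size clamping and alternation correction, per-wave signal quality
    grading (A-F) with adaptive skewness/kurtosis/standard-deviation
    thresholds, soft-label classification machinery with Kullback-Leibler
    loss, a configurable one-dimensional ResNet-Transformer classifier
    trained with a delayed learning-rate plateau schedule, and continuous
    glucose monitoring evaluation metrics (mean absolute relative difference
    and Clarke error grid analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
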