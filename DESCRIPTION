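Package: insightsleep
Title: Interpretable and Uncertainty-Aware Sleep Staging from Continuous Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Four-class sleep staging (wake, light, deep, REM) from overnight
    photoplethysmography (PPG). Implements the InsightSleepNet architecture - a
    causal local-attention module, an InceptionTime feature extractor, a
    time-distributed dense layer, a dilated temporal convolutional stack and a
    1x1 output head - together with the surrounding chain: EDF and annotation
    input, Chebyshev low-pass/detrend/normalise/resample signal conditioning to
    the fixed 1200x1024 epoch grid, class-weighted masked training,
    energy-score selective prediction with rejection, hypnogram metrics
    (accuracy, Cohen's kappa, weighted F1), sleep-parameter estimation, and a
    seeded synthetic overnight-PPG generator so the whole chain is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    xml2,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse,
    withr
Config/testthat/edition: 3
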