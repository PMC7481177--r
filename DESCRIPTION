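Package: ppgnet
Title: Multitask Convolutional Networks for Atrial Fibrillation Detection
    and Signal Quality Assessment in Wearable Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seed-deterministic toolkit for wearable photoplethysmography
    (PPG) rhythm analysis: simulation of sinus-rhythm and atrial-fibrillation
    PPG with baseline wander, amplitude modulation, beat-timing irregularity
    and additive Gaussian corruption; a preprocessing pipeline (bandpass,
    decimation, 25-s windowing, per-window [0,1] standardisation); rule-based
    and learned signal-quality scoring; convolutional denoising-autoencoder
    pretraining with encoder-weight transfer into a multitask 1-D
    convolutional classifier that jointly predicts signal quality and atrial
    fibrillation; weighted macro-averaged evaluation with quality filtering;
    and model inspection through gradient-weighted class activation maps and
    2-D embedding projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pracma,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
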