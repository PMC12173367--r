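Package: ecgbeatnet
Title: Dual-Scale Spectrogram Classification of ECG Heartbeats with a
    Squeeze-and-Excitation Multi-Input CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for heartbeat-level arrhythmia
    classification from single-lead ECG. Provides a seeded synthetic ECG
    generator with class-specific beat morphology, WFDB and CSV readers
    with AAMI-style label mapping, wavelet denoising (db4, SURE soft
    thresholding) and running-median baseline removal, a Pan-Tompkins-style
    R-peak detector, paired single-cycle/three-cycle beat segmentation
    (fixed-length and heart-rate adaptive with bicubic resampling),
    Kaiser-window STFT spectrograms, Mixup oversampling of minority
    classes, a two-branch convolutional network with squeeze-and-excitation
    channel attention and bicubic feature-map fusion trained with Adam, and
    a confusion-matrix metric suite (per-class accuracy, sensitivity,
    positive predictive value, F1, and macro averages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
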