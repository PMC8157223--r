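Package: eegid
Title: Deep Convolutional Descriptors for EEG Biometric Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for subject verification from multi-channel
    EEG: band-pass preprocessing, stride-based sliding-window augmentation,
    one-dimensional convolutional descriptor networks with optional
    squeeze-and-excitation channel attention, embedding extraction from the
    penultimate fully-connected layer, and genuine/impostor evaluation with
    DET curves, equal error rate and decidability. Includes a seeded
    synthetic EEG generator with controllable identity separability, a
    minimal EDF (European Data Format) reader/writer for the Physionet
    motor movement/imagery file layout, and a catalog of runnable
    evaluation scenarios (baseline, region/task protocols, cross-task and
    cross-individual splits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
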