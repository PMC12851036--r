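Package: gazeStrain
Title: Eyelid-Strain Gaze Decoding and Digital Strabismus Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of multidirectional eyelid-strain
    signals recorded by a wearable strain-sensing array during eye
    movements. Provides a biomechanically structured signal simulator
    (direction-dependent strain polarity, angle-monotone magnitudes,
    linear strain-to-resistance transduction, blink and expression
    artifacts), zero-phase high-pass preprocessing and ten-channel
    differential window expansion, a lightweight Inception-style 1-D
    convolutional direction classifier with per-direction multilayer
    perceptron angle regressors (plus polarity-rule and KNN-DTW
    baselines and few-shot subject calibration), a digitized Hess
    screen test with rule-based paretic-muscle localization and
    cover-uncover interpretation, and method-agreement statistics
    (intraclass correlation, Bland-Altman limits of agreement, folded
    empirical cumulative distributions) with subgroup stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
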