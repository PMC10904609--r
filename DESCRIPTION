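Package: HemoDecode
Title: Decoding Individual Finger Movements from fNIRS Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulation, preprocessing and multi-class decoding of
    functional near-infrared spectroscopy (fNIRS) finger-tapping
    experiments. Provides a block-design paradigm and dual-wavelength
    recording simulator with ground truth, a hemodynamic preprocessing
    pipeline (truncation, spike interpolation, coefficient-of-variation
    channel rejection, modified Beer-Lambert inversion, zero-phase
    Butterworth band-pass filtering, temporal-derivative distribution
    repair and normalization), stimulus-locked event-average feature
    extraction, and a ten-model classifier suite spanning discriminant
    analysis, penalized multinomial regression, tree ensembles and
    deep time-series networks, including an inception-style
    one-dimensional convolutional architecture ("Hemo-Net").
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    nnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
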