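Package: thermoshock
Title: Noncontact Hemodynamic Shock Prediction from Thermal Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for continuous noncontact monitoring of hemodynamic
    shock in pediatric intensive care from single-channel thermal video.
    Screens 1 Hz frames for blanket cover, detects and masks non-patient
    persons, segments abdomen and feet with a compact encoder-decoder
    network, extracts the center-to-peripheral temperature difference (CPD)
    as a percent gradient, labels time points with the age-adjusted
    pediatric shock index (SIPA), builds 256-second CPD plus heart-rate
    windows with linear-interpolation imputation and SMOTE balancing, and
    classifies them with a recurrent (LSTM) sequence model to predict shock
    status up to six hours ahead. Includes a synthetic thermal-scene and
    vitals generator with planted shock structure so every stage is
    trainable and testable without clinical recordings, plus patient-wise
    stratified cross-validation and threshold-free and Youden-index metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
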