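Package: felidniche
Title: Spatio-Temporal Niche Partitioning Analysis for Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing resource partitioning in sympatric carnivore
    guilds from camera-trap survey data. Implements independent-detection
    filtering, multi-scale habitat-occurrence modelling with circular
    focal-window statistics, AIC-based scale optimization, all-subsets
    logistic regression with Akaike-weight model averaging, probability of
    occurrence surfaces, felid/candidate-prey co-occurrence models, circular
    (von Mises) kernel density estimation of diel activity, coefficients of
    temporal overlap (Delta 1 and Delta 4) with smoothed-bootstrap confidence
    intervals, and a synthetic landscape/community generator for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
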