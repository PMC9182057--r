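Package: nirsel
Title: Wavelength Selection and PLS Calibration for Near-Infrared Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A chemometrics toolkit for building quantitative near-infrared
    (NIR) calibration models for plant-biomass constituents such as cellulose
    and hemicellulose. Implements NIPALS PLS1 regression with Monte-Carlo and
    k-fold cross-validation, spectral pretreatments (Savitzky-Golay,
    multiplicative scatter correction, standard normal variate, first
    derivative, normalization) with automatic selection by minimum RMSECV,
    MCCV-based abnormal-sample screening, SPXY calibration/validation
    partitioning, and five wavelength-selection strategies: backward interval
    PLS (BIPLS), competitive adaptive reweighted sampling (CARS), genetic
    simulated annealing (GSA), and the hybrid chains BIPLS-CARS, BIPLS-GSA and
    CARS-GSA. Includes a synthetic corn-stover-like spectra generator with
    known ground truth so every pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
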