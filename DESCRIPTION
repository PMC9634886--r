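Package: monoiso
Title: Monoisotopic Mass Determination from Resolved Isotopic Envelopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the monoisotopic mass of intact proteins from resolved
    isotopic envelopes. Implements an aggregated isotopic distribution engine
    for CHNOS chemical formulas, a linear predictor on the spectrum's average
    mass and variance, grid-based rounding of the initial estimate using
    circular statistics on the ~1 Da inter-cluster spacing, and an
    averagine-scaling stage that matches a simulated spectrum to an
    experimental envelope by Wasserstein distance. Includes a synthetic
    proteome generator to retrain the linear models and reproduce the
    evaluation statistics at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
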