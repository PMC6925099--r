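Package: chromrt
Title: Retention Time Prediction, Cross-Method Projection and
    Accurate-Mass Annotation for Reverse-Phase LC-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-retention relationship (QSRR)
    modelling in reverse-phase liquid chromatography. Provides circular
    (Morgan-type) binary fingerprints from SDF or SMILES structures, a deep
    fully-connected regression model mapping fingerprints to retention time,
    a Tanimoto k-nearest-neighbour median baseline with similarity-stratified
    statistical comparison, polynomial projection of predicted retention
    times onto other chromatographic methods, and accurate-mass candidate
    annotation with ROC-based retention-time error filtering and top-k
    ranking. Includes a seeded synthetic data generator emulating a large
    fingerprint/retention-time library and external chromatographic methods,
    so the whole pipeline can be exercised and validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
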