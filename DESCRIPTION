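Package: sonoptim
Title: Design, Surrogate Modelling and Optimization of Ultrasonic-Assisted
    Polysaccharide Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing ultrasonic-assisted alkaline extraction of
    fungal polysaccharides with design-of-experiments surrogates. Builds full
    central composite designs with practical axial spacing, simulates yield
    responses from a published fitted quadratic surface, screens and partitions
    run tables (Mahalanobis outlier screen, min-max scaling, stratified
    splitting, variance inflation factors), fits second-order response-surface
    models with a complete ANOVA including lack-of-fit and predicted R-squared,
    trains epsilon-insensitive support vector regression through a hand-written
    SMO dual solver with nested cross-validated grid search, fuses permutation,
    partial-dependence and support-vector feature importance, maximizes fitted
    surrogates over box constraints with multistart local search, and computes
    production-rate, specific-energy and carbon-intensity process metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    nortest,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
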