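Package: erpsep
Title: Separating Categorical and Covariate Effects in Single-Trial ERP
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mass-univariate two-level linear modeling of single-trial
    event-related potentials (ERPs) for detecting and quantifying
    covariate-induced bias in category-evoked EEG responses.  Provides a
    synthetic multi-subject ERP generator with ground-truth effect masks,
    per-subject ordinary-least-squares beta and R-squared maps over
    channels by timepoints, dimensionality-matched "naive" baseline models
    with random covariates, robust second-level inference (Yuen trimmed-mean
    t-tests, bootstrap spatio-temporal cluster correction, threshold-free
    cluster enhancement), and an explained-variance decomposition that
    tests whether categorical and covariate effects are separable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
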