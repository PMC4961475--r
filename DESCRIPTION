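Package: heighttrends
Title: Hierarchical Bayesian Estimation of Adult Height Trends by Birth Cohort
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates mean adult height (at age 18) by country, sex, and birth
    cohort from heterogeneous population-based survey summaries. Implements a
    hierarchical Bayesian model in which country trends are nested in regions,
    super-regions and the world, with linear plus second-order random-walk
    cohort components, a linear age-drift term, and systematic-offset and
    extra-variance components for subnational and community data sources.
    Includes a blocked Gibbs MCMC sampler, Brooks-Gelman-Rubin convergence
    diagnostics, a synthetic survey-database generator for testing, a
    stratified country-holdout validation protocol, and reporting utilities
    (century change, rankings, sex gaps, trend plots).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    ggplot2,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
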