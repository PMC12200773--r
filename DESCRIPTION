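Package: droughtlink
Title: Linking Gridded Drought Exposure to Survey Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterises drought from monthly gridded SPEI (Standardized
    Precipitation-Evapotranspiration Index) series using run-length based
    duration (count) and intensity (sum) definitions, drought cycles, a
    standardised dryness intensity, and four sample-relative exposure
    categories over 48-month pre-interview windows; aggregates cell-level
    measures to administrative districts with coverage weights and attaches
    exposure profiles to survey respondents; and fits varying-intercept
    Bayesian logistic regressions of a binary outcome on each exposure
    category via an adaptive Metropolis-within-Gibbs sampler, with split-Rhat
    and bulk effective-sample-size convergence diagnostics, posterior
    predictive checks, survey-weighted prevalence estimation, and a synthetic
    data generator that provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    lme4,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
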