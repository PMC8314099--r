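Package: commoncp
Title: Bayesian Detection of Common Change-Points in Seasonal Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits adaptive Bayesian change-point models to unbalanced
    longitudinal panel data such as quarterly antibiotic consumption
    surveillance series. The model is a non-linear mixed model combining a
    piecewise-linear trend with K data-driven common change-points, a sine
    wave with time-varying amplitude for seasonality, and country-level
    random effects. Fitting is by a Metropolis-within-Gibbs sampler with
    conjugate updates for the linear structure; models with different
    numbers of change-points are compared via the Deviance Information
    Criterion in both its pD and pV variants. Includes a synthetic panel
    generator that emulates unbalanced surveillance data, posterior
    summaries with calendar-quarter translation of change-point locations,
    and population- and country-level prediction curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    coda,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
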