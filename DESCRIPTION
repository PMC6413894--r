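Package: underfive
Title: Age Patterns of Under-5 Mortality from Full Birth Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation, calibration, smoothing, and forecasting of monthly
    age patterns of under-5 mortality from full-birth-history survey data.
    Provides a synthetic full-birth-history generator with known ground-truth
    mortality surfaces, direct life-table estimation of monthly death rates,
    proportional calibration of survival probabilities to external
    neonatal/infant/under-5 rates, penalized Poisson P-spline smoothing of
    the age-by-time mortality surface, a limited-data Lee-Carter model with
    random-walk-with-drift forecasts and three error-bound widths, annual
    rates of reduction, and classification of countries against the SDG-3
    neonatal and under-5 mortality targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
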