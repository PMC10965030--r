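Package: frailtyq
Title: Longitudinal Quantile Reference Curves for Frailty Trajectories in
    Mortal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds deficit-accumulation Frailty Index (FI) trajectories from
    longitudinal item panels and estimates their conditional quantiles with
    age while accounting for death and intermittent missingness. Provides a
    weighted quantile-regression estimator (exact interior-point solution of
    the check-loss program) under an independence working assumption,
    stabilized inverse-probability-of-observation weights estimated by
    logistic regression under an unconditional missing-at-random assumption,
    a longitudinal (cluster) bootstrap with single-coefficient and
    cross-quantile Wald tests, sex- and education-specific reference curves
    with percentile confidence bands, and a synthetic mortal-cohort
    generator with closed-form true quantile coefficients for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
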