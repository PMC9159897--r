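Package: rehabspc
Title: Individual Control Charts and Outcome Prediction for Repeated
    Cognitive Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Change detection for repeated cognitive outcome measurements
    in rehabilitation using statistical process control (SPC) individual
    charts with a two-observation frozen baseline and pooled-baseline sigma,
    run rules for significant improvement (single point beyond 3 sigma; two
    of three consecutive points at or beyond 2 sigma), and dichotomization of
    each patient as CHANGE or NO CHANGE. Includes the downstream
    predictor-association suite (Pearson chi-square with Cramer's V and
    Woolf odds-ratio intervals, Fisher's exact test, one-way ANOVA with eta
    squared, Pearson correlation screening, linear-probability regression,
    and the linear-by-linear trend statistic), a synthetic cohort generator
    emulating serial-addition attention-test trajectories with early
    learning effects and latent responders, and operating-characteristic
    (power) analysis of the detection rules.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
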