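Package: actisleep
Title: Actigraphy Sleep Quotas, Circadian Rhythm Metrics and Group Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 1-minute epoch wrist actigraphy from field
    cohorts: a weighted moving-window sleep/wake scorer with per-night sleep
    quotas (TST, TTST, WASO, efficiency, fragmentation index), non-parametric
    circadian rhythm analysis (IS, IV, M10, L5, relative amplitude), two-group
    contrasts via default-prior (JZS) Bayes factors, Welch t-tests and variance
    F-tests with circular statistics for clock times, random-intercept linear
    mixed models with AIC-weighted shrinkage model averaging, and functional
    linear modelling of 24-h activity curves with pointwise permutation
    F-tests. Includes a synthetic cohort generator that emulates a
    two-location (village/forest) study design so the full pipeline is
    testable without access to raw device exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    lme4,
    withr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
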