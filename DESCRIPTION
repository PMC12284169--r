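Package: bagrate
Title: Longitudinal Brain-Age-Gap Rate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex- and tissue-stratified unbiased brain-age modelling from
    imaging-derived phenotypes (IDPs), longitudinal brain-age-gap (BAG)
    rate-of-change estimation, and the associated group and interaction
    statistics: covariate deconfounding with training-set weights, SVD
    dimensionality reduction, age-bias-corrected (orthogonalised) BAG,
    repeated k-fold cross-validation, two-factor permutation ANOVA with
    Freedman-Lane exchangeability, Wilson calibration intervals,
    Benjamini-Hochberg FDR, ICC(2,1) scan-rescan reproducibility, sliding
    window cognitive-change curves, and a seeded synthetic-cohort generator
    with injectable group effects for parameter-recovery testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
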