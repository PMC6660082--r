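Package: ctvar
Title: Variance Components and Reference Intervals for Longitudinal qRT-PCR Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal quantitative RT-PCR biomarker
    panels: replicate-level cycle-threshold (Ct) quality control, delta-Ct
    normalization against an adaptively selected endogenous reference panel
    or an exogenous spike-in control, one-way random-effects variance
    decomposition into between- and within-donor components (method-of-moments
    ANOVA and restricted maximum likelihood), and 95% reference intervals and
    fold-change spans on the relative-expression scale using a t-distribution
    with degrees of freedom derived from the clustered-design effective sample
    size. Includes a synthetic-data generator with recorded ground truth so
    that every pipeline stage can be validated by parameter recovery.
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
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
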