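Package: cgmhypo
Title: CGM Glycaemic Variability, Hypoglycaemia Detection and C-Peptide
    Group Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studies relating endogenous insulin
    secretion (random plasma C-peptide) to hypoglycaemia risk in
    insulin-treated diabetes.  Provides per-24-hour quality control of
    continuous glucose monitoring (CGM) traces against self-monitored
    blood glucose calibrations, glycaemic variability metrics (mean, SD,
    MAGE, LBGI), threshold- and duration-based hypoglycaemia episode
    detection with day/night partitioning, scoring and frequency
    recoding of the Clarke hypoglycaemia awareness questionnaire, and
    the group-contrast statistics (paired t, chi-square, exact Poisson
    rate intervals, rate-ratio z tests, adjusted regression models).  A
    calibrated stochastic cohort simulator (Ornstein-Uhlenbeck
    background with circadian modulation and an injected excursion
    process) makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
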