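Package: eprocua
Title: Trial-Based Cost-Utility Analysis of Electronic Patient-Reported
    Outcome Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-based stochastic cost-utility analysis of
    electronic patient-reported outcome (ePRO) interventions run alongside
    randomized controlled trials. Maps EORTC QLQ-C30 dimension scores to
    EQ-5D-3L response probabilities and expected utilities under pluggable
    value sets, computes per-patient intervention and health-care costs in a
    common currency-year, derives QALY losses over the treatment period,
    estimates incremental cost-effectiveness ratios (ICERs) under three cost
    bases with nonparametric bootstrap uncertainty and cost-effectiveness
    planes, categorizes acute-care ICD-10 codes, and fits overdispersion-aware
    utilization regressions. Includes a seed-reproducible synthetic two-arm
    cohort generator emulating the statistical structure of ePRO trials so the
    whole pipeline is testable without access to administrative care data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
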