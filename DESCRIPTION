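Package: outcomepay
Title: Value-Based Remuneration Modelling for Psoriasis Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and stress-testing value-based remuneration
    schemes for psoriasis (PsO) and psoriatic arthritis (PsA) hospital care.
    Implements two patient-level payment models built on anticipated PASI
    (Psoriasis Area and Severity Index) after treatment: a PASI-difference
    model with a patient-priority correction factor, and a weighted
    outcome-goal model with a standardized-deviation projection of anticipated
    sub-outcomes. A budget-calibrated scaling factor guarantees that total
    payout never exceeds a department-level financial limit, and a Monte-Carlo
    harness probes the scheme's incentive properties (budget compliance,
    effort monotonicity, and the collusion "side effect" of system-wide
    calibration). The package also provides a matched (1:2) case-control
    registry pipeline (index dates, cost/income eligibility and censoring
    rules, WHO-chapter comorbidity pooling, conditional logistic contrasts)
    and a concept-mapping workflow (card-sort co-occurrence, nonmetric
    multidimensional scaling, Ward clustering, importance-rating summaries),
    together with seeded synthetic-data generators for all inputs so every
    analysis runs without access to national health registries.
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
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    truncnorm,
    utils,
    withr,
    yaml
Suggests:
    broom,
    mclust,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
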