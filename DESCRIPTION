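Package: ramcea
Title: Markov Cohort Cost-Utility Model for Sequential Rheumatoid
    Arthritis Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cohort state-transition (Markov) model for cost-utility
    analysis of biologic, targeted synthetic and biosimilar DMARDs combined
    with methotrexate against standard of care in rheumatoid arthritis
    patients with high disease activity. Provides Weibull proportional-hazards
    estimation of time-dependent transition probabilities from right-censored
    event histories, a 6-month-cycle cohort engine with treatment-sequencing
    rules (inadequate-response switching, remission tapering, adverse-event
    interruption) and life-table mortality adjusted by a disease-activity
    hazard ratio, discounted costing and QALY aggregation with incremental
    cost-effectiveness ratios, one-way (tornado) and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and synthetic-data
    generators for every model input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr
Config/testthat/edition: 3
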