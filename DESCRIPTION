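Package: erpcea
Title: Trial-Based Cost-Effectiveness Analysis of Enhanced Recovery Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-alongside health-economic evaluation of an
    enhanced recovery program (ERP) versus standard perioperative care,
    developed around open liver resection. Provides patient-level
    micro-costing from unit-cost schedules, EQ-5D-3L utility scoring and
    28-day quality-of-life area-under-curve analysis with QALY
    annualization, Kaplan-Meier survival with sample-size-dependent Fisher
    exact or chi-square comparisons, a decision-tree plus three-state
    Markov cohort cost-effectiveness model with life-table background
    mortality and discounting, Monte Carlo probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, and a synthetic
    two-arm trial generator for fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    survival,
    jsonlite,
    yaml,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
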