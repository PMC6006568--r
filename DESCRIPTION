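Package: bicea
Title: Cost-Effectiveness Analysis of Brief Substance-Use Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness analysis for brief
    substance-use interventions delivered in emergency departments.
    Implements ingredients-based provider and patient costing with capital
    annuitization and counsellor time-share allocation, expected cost and
    effect per screened patient for screening-plus-referral strategies
    (control, motivational interviewing, and motivational interviewing
    combined with problem solving therapy), incremental cost-effectiveness
    ratios with strict and extended dominance handling, one-way and
    scenario sensitivity analyses over screening positivity, acceptance and
    counselling excess capacity, and a synthetic trial-cohort generator so
    the whole pipeline runs end-to-end without patient-level trial data.
    Ships a worked configuration for a South African emergency-department
    brief-intervention study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
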