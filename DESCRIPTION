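Package: osteomark
Title: Lifetime Markov Cohort Cost-Effectiveness Model for Osteoporosis
    Treatment Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lifetime Markov cohort model for the cost-effectiveness of
    osteoporosis treatment sequences in postmenopausal women, comparing
    10-year denosumab against alendronate given as 5 years on treatment, a
    2-year drug holiday and 3 further years on treatment, and against no
    treatment, from a United States third-party payer perspective. Fracture
    risk is composed per 6-month cycle as the product of general-population
    incidence, a disease-related relative risk (bone mineral density gradient
    or prior-fracture relative risk) and a time-dependent treatment risk
    reduction subject to real-world persistence and a linear efficacy offset
    after discontinuation. The package provides the cohort engine with
    tunnel states for the 8-year post-fracture excess-mortality window, an
    individual-level microsimulation oracle implementing identical rules,
    discounted cost and quality-adjusted life-year accrual with downstream
    fracture corrections, scenario grids over treatment and holiday
    durations, one-way sensitivity analysis, and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Inputs that the
    primary sources do not print (female life table, age-specific fracture
    incidence, population mean T-scores, nursing-home admission after hip
    fracture) ship as clearly flagged synthetic defaults generated in code.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
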