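# osteomark

A lifetime Markov cohort model for the cost-effectiveness of osteoporosis
treatment sequences in postmenopausal women, from a US third-party payer
perspective. The base case compares **10-year denosumab** against
**alendronate given as 5 years on treatment, a 2-year drug holiday and 3
further years on treatment**, and against **no treatment**, for a cohort
entering at age 72 with a T-score of −2.5 and prevalent vertebral fracture
in 23.6%.

It is written for health-economics analysts who need a tested, scriptable
implementation of this model class: eight health states with a fracture
severity hierarchy (hip > vertebral > wrist > other), 6-month cycles, and
per-cycle fracture risk composed as

```
p = 1 − exp(−½ · rate_gen(site, age) · RR_disease · RR_treatment)
```

where `RR_disease` is either the BMD gradient of risk per SD
(`g^(T̄(age) − T)`) or the prior-fracture relative risk, and
`RR_treatment` is the time-dependent efficacy RR subject to real-world
persistence and a linear post-discontinuation offset (at most 1 year for
denosumab, 2 for alendronate, shortened for early discontinuers). Excess
mortality after hip, vertebral and other fractures persists 8 years
(30% attributable to the fracture), carried by half-year tunnel states.
Outputs are discounted costs by category, life-years, QALYs (including a
downstream-fracture correction for events the hierarchy would otherwise
drop), ICERs with dominance classification, scenario grids over
treatment/holiday durations, one-way sensitivity tables, and a 1000-draw
probabilistic sensitivity analysis with cost-effectiveness acceptability
curves.

Inputs the primary sources do not print — the female life table,
age-specific fracture incidence, population mean T-scores and nursing-home
admission after hip fracture — ship as clearly flagged **synthetic
stand-ins** generated in code (see `vignette("model-methods")` for what
they do and do not allow you to conclude). Replace them with measured
tables via a parameter bundle (`write_bundle()` / `load_parameters()`) for
numeric replication work.

## Worked example

```r
library(osteomark)

params <- default_parameters()      # published inputs + synthetic stand-ins
ce <- ce_analysis(params)           # denosumab vs no treatment vs alendronate
ce
#> <osteo_ce>
#> # A tibble: 3 × 5
#>   strategy          cost_total ev_any    ly  qaly
#>   <chr>                  <dbl>  <dbl> <dbl> <dbl>
#> 1 denosumab_10y         51560.   1.31  11.8  8.45
#> 2 no_treatment          49026.   1.41  11.8  8.35
#> 3 alendronate_5_2_3     46138.   1.34  11.8  8.40
#> # A tibble: 2 × 7
#>   intervention  comparator        delta_cost delta_qaly delta_ly    icer status
#>   <chr>         <chr>                  <dbl>      <dbl>    <dbl>   <dbl> <chr>
#> 1 denosumab_10y no_treatment           2534.     0.103    0.0427  24507. icer
#> 2 denosumab_10y alendronate_5_2_3      5422.     0.0537   0.0226 100949. icer
```

Each row of the first table is one strategy: total discounted lifetime
cost per patient, cumulative fractures of any site per patient, discounted
life-years and QALYs. The second table gives the pairwise incrementals of
the intervention (first strategy): under the synthetic stand-in inputs,
10-year denosumab costs $5,422 more than the alendronate sequence and
yields 0.054 additional QALYs per patient — an ICER of about $100,900 per
QALY gained, which is cost-effective at a $150,000/QALY willingness to pay
but not at $100,000.

Other entry points follow the same pattern and return tibbles:

```r
run_trace(strategy_denosumab(), params)            # per-cycle cohort trace
scenario_grid(params)                              # treatment/holiday grid
owsa(params, owsa_default_variants())              # one-way sensitivity
ps <- psa(params, n = 1000, seed = 1)              # probabilistic SA
glance(ps)                                         # P(cost-effective) at $100k/$150k
autoplot(ps); plot_ceac(ps)                        # scatter and CEACs
simulate_cohort(strategy_denosumab(), params,      # microsimulation oracle
                n = 200000, seed = 1)
```

`apply_override(params, "config.start_age", 65L)` changes any single
input by dotted path; every sensitivity-analysis row is such an override.

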