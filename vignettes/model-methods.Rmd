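---
title: "The osteomark cohort model: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The osteomark cohort model: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomark)
```

## The decision problem

osteomark implements a lifetime Markov cohort model for the
cost-effectiveness of osteoporosis treatment sequences in postmenopausal
women, from a US third-party payer perspective. The base case compares
three strategies for a cohort entering at age 72 with a femoral-neck
T-score of −2.5 and a 23.6% prevalence of vertebral fracture:

* **10-year denosumab** (60 mg subcutaneously every 6 months),
* **alendronate 5 + 2 + 3**: 5 years on oral alendronate, a 2-year drug
  holiday, then 3 further years on treatment,
* **no treatment**.

The model advances in 6-month cycles to a maximum age of 100 (a fixed-year
horizon is available as a configuration switch), discounting costs and
QALYs at 3% per year.

## Health states and hierarchy

Eight health states are modeled: well, acute hip / vertebral / wrist /
other fracture, post-hip, post-vertebral, and dead. Competing fractures
within a cycle resolve by a severity hierarchy (hip > vertebral > wrist >
other). Wrist and other fractures have no chronic state; survivors return
to well after the one-year acute window. Hip and vertebral fractures lead
to permanent post-fracture states.

Because a patient occupying a hip or vertebral state cannot simultaneously
move to a lower-hierarchy state, lower-hierarchy fractures sustained there
would be lost by a naive chain. The engine therefore records **downstream
fracture events**: for occupancy in the hip, vertebral, post-hip and
post-vertebral states, expected lower-site events (occupancy × the site's
marginal cycle probability) accrue their full one-year acute cost and an
acute disutility, without changing state. The disutility is derived in
three steps: the occupied state's utility, times one minus the lower
site's year-1 multiplier, applied over one year.

## Fracture risk composition

The per-cycle probability of a fracture at site $s$ and age $a$ is

$$p_s = 1 - \exp\!\big(-\tfrac12\, r_s(a)\, \mathrm{RR}^{dis}_s(a)\,
\mathrm{RR}^{tx}_s(t)\big),$$

the exponential conversion of an annual rate composed of three factors:

1. $r_s(a)$ — the general-population female incidence rate;
2. $\mathrm{RR}^{dis}_s$ — the disease-related relative risk. Patients
   without prior fracture carry the BMD gradient
   $g_s^{\,\bar T(a) - T}$, where $g_s$ is the risk gradient per SD of hip
   BMD (hip 2.60, vertebral 1.80, wrist 1.40, other 1.60) and $\bar T(a)$
   the population mean T-score. Patients with a prior fracture carry
   `max(BMD gradient, adjusted prior-fracture RR)`; the prior-fracture RRs
   (vertebral 4.40, wrist 1.40, other 1.90, hip age-keyed) are adjusted
   downward by 10% because they partly reflect low BMD. A `"multiply"`
   switch (`config$disease_rr_rule`) composes the two factors
   multiplicatively instead, for users who read the 10% adjustment as a
   double-counting correction that licenses the product; the default
   follows the max rule so that the adjusted prior-fracture RR acts as a
   floor rather than a multiplier.
3. $\mathrm{RR}^{tx}_s(t)$ — the treatment effect (next section).

Age-keyed tables use step lookup at the largest key at or below the
current age; linear interpolation is available via `config$age_lookup`.

## Treatment effect, persistence and offset

Efficacy is time-dependent: pooled RRs versus placebo at 12, 24 and 36
months of treatment, carried forward at the 36-month value thereafter. The
RR in force during a cycle is selected by cumulative on-treatment months
at the end of the cycle, so patients discontinuing after one cycle carry
the 12-month RR — the convention that slightly favors discontinuers.

Persistence follows observed 6-monthly proportions over 36 months
(denosumab 100% → 38.0%; alendronate 100% → 17.2%), evaluated at the start
of each cycle for denosumab (aligned with its injections) and at the cycle
midpoint — linearly interpolated between observations — for oral
alendronate. Beyond 36 months, three extrapolations are available:
holding the final interval's retention ratio (`last_value`, the base case,
and `last_interval_rate`, listed separately because sensitivity analyses
treat them as distinct options; on 6-monthly data they coincide), or the
constant ratio implied by the 36-month value (`overall_rate`,
$0.172^{1/6}$ per half-year for alendronate).

Each cycle's discontinuation flow spawns a stratum that remembers months
on treatment at discontinuation. Its fracture RR returns to 1 linearly
over the *effective offset* — the smaller of time on treatment and the
drug maximum (denosumab 1 year, alendronate 2) — evaluated at the cycle
midpoint of time off treatment, which is exact for a linear decay.
During the scheduled drug holiday everyone, persistent or not, decays by
the same rule with the clock frozen at holiday start. On re-initiation the
persistence clock resumes from its value at holiday start (no reset to
100%); this conservative choice is switchable
(`config$persistence_reset_after_holiday`). Fully offset strata merge into
a single untreated pool, which keeps the state space small.

## Mortality

Baseline per-cycle mortality is $1-(1-q_a)^{1/2}$ from a female period
life table. After hip, vertebral and other fractures (wrist carries no
published excess), an age-keyed mortality RR applies for 8 years, scaled
by the fraction of excess mortality attributable to the fracture itself
(30%; 0–100% in sensitivity analyses):
$q = q_{cycle}\,[1 + 0.30\,(\mathrm{RR}-1)]$. The 8-year window is carried
by half-year tunnel compartments in the post-hip/post-vertebral states,
by the acute and convalescent cycles plus a well-state clock for "other"
fractures, and adapts its depth when the window is varied (3, 5, 10 years
or lifetime).

An incident vertebral fracture sets a lifetime flag. Flagged occupancy in
the hip and post-hip states carries the vertebral excess-mortality
component additively while inside the hip window, and the chronic
vertebral utility multiplier for life — the long-run consequence of a
vertebral history that a memoryless chain would drop on transition to the
hip states. The engine tracks this flag exactly per compartment rather
than through the cohort-level weighting approximation
(`prior_vf_weight()`, exported for reference: the incremental vertebral
fracture proportion over the baseline non-prevalent fraction). Prevalent
vertebral fractures at entry raise fracture risk through the
prior-fracture RR but, being pre-model history of unknown age, do not
carry the incident-fracture mortality or utility consequences.

## Costs and QALYs

Per cycle and per unit occupancy:

* **Drug and monitoring** — half a year of drug acquisition plus the
  monitoring schedule (denosumab: 2 nurse visits/yr for administration;
  all treatments: 1 physician visit/yr, 0.5 DXA scans/yr), scaled by the
  on-treatment stratum mass; zero during holidays and after
  discontinuation.
* **Fracture treatment** — the year-1 cost of a routed fracture is split
  evenly over the acute and first post cycle, mirroring the two-cycle
  disutility window; chronic post-hip/post-vertebral occupancy accrues
  half the year-2+ cost per cycle for life; downstream events accrue the
  full year-1 cost in their cycle. Age bands (50–64 / 65+) are read at the
  accrual cycle.
* **Long-term care** — hip fracture events only: admission probability ×
  mean stay × per-day cost, as a one-time expected cost at the event
  (the stay-duration profile is never published; the lump-sum expected
  value is order-correct and documented as such).
* **QALYs** — age-band baseline utility times the state multiplier
  (hip 0.550/0.860, vertebral 0.680/0.850, wrist-or-other 0.830 acute
  only), times half a year, minus downstream disutilities.

Accrual happens on the post-transition state each cycle (death before
fracture, both at cycle start — stated explicitly since the event order
within a cycle is otherwise ambiguous), discounted at cycle end;
`config$discount_timing` switches to start- or mid-cycle discounting. No
half-cycle correction is applied in the base engine; the alendronate
midpoint persistence convention covers the one place the source material
implies one.

## The microsimulation oracle

`simulate_cohort()` is an individual-level Monte Carlo implementation of
the identical rules, sharing the per-cycle input precomputation
(`model_frame()`) with the cohort engine so the two cannot drift apart on
inputs, while each individual carries exact state, clock, flag and stratum
variables. It exists to validate the cohort engine: expectations must
agree within Monte Carlo error, and the acceptance suite enforces
agreement within 3 standard errors at 200,000 individuals on cost, QALYs,
life-years and per-site events, for the base case and for randomly
sampled parameter sets. During development this comparison caught a
genuine engine defect (a silently recycled per-site residual-efficacy
vector), which is precisely the failure mode an independent oracle is
for.

## Synthetic stand-in inputs

Four inputs the primary sources do not print ship as documented
assumptions, generated in code (`gen_*` functions) and flagged `ASSUMED`
when serialized:

* a **female life table** from a Gompertz–Makeham law
  ($q = 3\times10^{-4} + 2\times10^{-5} e^{0.094x}$), giving a life
  expectancy at 72 of about 16 years;
* **general-population fracture incidence**, exponential in age per site,
  with hip rising ten-fold from 55 to 85 and anchors chosen once so the
  untreated cohort accumulates on the order of one fracture per patient
  over a lifetime (about 1.4 under the defaults);
* **population mean T-score**, declining linearly (−0.9 SD at 65 to
  −1.8 SD at 85);
* **nursing-home admission** after hip fracture (20%, 180-day mean stay).

These stand-ins reproduce the *structure* the analysis assumes — not any
measured population. Passing tests therefore demonstrate correct model
mechanics, calibrated magnitudes and correct directional behavior, but
not numeric replication of published results, which requires transcribing
the measured life table, post-fracture mortality RRs and incidence
schedule into a parameter bundle (`write_bundle()` /
`load_parameters()`). With the stand-ins, the deterministic
denosumab-vs-alendronate ICER computed by `scripts/acceptance.R` lands
within a few percent of the published figure, while the vs-no-treatment
comparison is more sensitive to the absolute fracture burden and does not
reproduce the published dominance.

## Numerical choices and problem sizes

* Rates compose multiplicatively and convert to probabilities
  exponentially, so probabilities stay in $[0,1)$ under any RR product;
  death probabilities are clipped at 1 (with a warning) only if an extreme
  configuration pushes them past it.
* Compartment masses are aggregated by integer keys each cycle; mass
  conservation (occupancy + cumulative deaths = 1) is asserted at
  $10^{-10}$ every cycle and the engine stops early once the cohort is
  extinct.
* The PSA uses lognormal efficacy RRs moment-matched so the *mean* equals
  the point estimate (not the median), beta distributions moment-matched
  by mean and SE for proportions and utilities (variance clipped with a
  warning when incompatible), and zero-truncated normals for fracture
  costs; standard errors default to 10% of point estimates. Sampled
  persistence curves are forced nonincreasing by a running minimum.
  Common random numbers apply across strategies within a draw.
* Default problem sizes: 56 cycles per trace (~0.1 s), 1000 PSA
  iterations (~5 minutes), 200,000 oracle individuals per validation run
  (~20 s). The test suite completes in under 5 minutes.

## Known limitations

* No imminent-risk escalation by time since fracture, no covariate
  heterogeneity beyond the prior-fracture/vertebral flags, no treatment
  switching, no societal-perspective costs.
* Downstream fracture events feed cost and disutility only; they do not
  trigger excess mortality or state change, so lower-site burdens remain
  slightly conservative.
* The "other"-fracture mortality window is tracked through the well-state
  clock and truncates at the configured window even under the lifetime
  variant for hip/vertebral.
* Stand-in inputs carry no epidemiological authority; see above.

```{r example}
params <- default_parameters()
ce <- ce_analysis(params)
tidy(ce)
glance(ce)
```
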