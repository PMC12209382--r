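# Shared fixtures. The default parameter set is deterministic, so it is
# built once per test run.

base_params <- default_parameters()

# Parameter set with no background mortality before the terminal age and no
# fracture risk: isolates bookkeeping from epidemiology.
inert_params <- local({
  p <- base_params
  p$mortality$life_table$q[p$mortality$life_table$age < 110] <- 0
  p$incidence$rate <- 0
  validate_parameters(p)
})

# A "treatment" with no effect and no cost: efficacy RR 1 everywhere,
# zero drug/monitoring costs. Used for neutral-treatment equivalence.
neutral_params <- local({
  p <- base_params
  p$efficacy$rr <- rep(1, nrow(p$efficacy))
  validate_parameters(p)
})

neutral_denosumab <- local({
  s <- strategy_denosumab()
  s$annual_drug_cost <- 0
  s$nurse_visits_per_year <- 0
  s$physician_visits_per_year <- 0
  s$dxa_per_year <- 0
  s
})

# z-scores of cohort-engine outputs against a microsimulation summary
oracle_z <- function(eval_row, ms) {
  want <- c(cost = eval_row$cost_total, qaly = eval_row$qaly,
            ly = eval_row$ly, ev_hip = eval_row$ev_hip,
            ev_vert = eval_row$ev_vert, ev_wrist = eval_row$ev_wrist,
            ev_other = eval_row$ev_other)
  got <- stats::setNames(ms$summary$mean, ms$summary$metric)
  se <- stats::setNames(ms$summary$se, ms$summary$metric)
  ifelse(se[names(want)] > 0,
         (want - got[names(want)]) / se[names(want)],
         want - got[names(want)])
}
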