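# Cohort engine: mortality, bookkeeping, hierarchy routing, conservation.

test_that("death_prob: baseline, attribution scaling, closed form", {
  p <- apply_override(base_params, "mortality.life_table.72", 0.04)
  expect_equal(death_prob(72, "well", params = p), 1 - 0.96^0.5)
  expect_equal(1 - 0.96^0.5, 0.020204, tolerance = 1e-4)
  # RR = 1 leaves baseline untouched even in a fracture state
  p1 <- p
  p1$mortality$rr_post_fx$rr <- rep(1, nrow(p1$mortality$rr_post_fx))
  expect_equal(death_prob(72, "hip_fx", 0, p1), 1 - 0.96^0.5)
  # attribution 0 reduces to baseline regardless of the RR
  p0 <- apply_override(p, "config.excess_mortality_attribution", 0)
  expect_equal(death_prob(72, "hip_fx", 0, p0), 1 - 0.96^0.5)
  # outside the 8-year window the excess vanishes
  expect_equal(death_prob(72, "post_hip", 16L, p), 1 - 0.96^0.5)
  expect_gt(death_prob(72, "post_hip", 15L, p), 1 - 0.96^0.5)
})

test_that("prior_vf_weight is the incremental/baseline quotient", {
  expect_equal(prior_vf_weight(0, 0.764), 0)
  expect_equal(prior_vf_weight(0.1, 1 - 0.236), 0.1309, tolerance = 1e-4)
  expect_equal(prior_vf_weight(0.764, 0.764), 1)
  expect_error(prior_vf_weight(0.1, 0), "> 0")
})

test_that("mass is conserved and occupancy stays nonnegative", {
  for (s in list(strategy_denosumab(), strategy_alendronate(),
                 strategy_no_treatment())) {
    tr <- run_trace(s, base_params)
    cy <- tr$cycles
    expect_true(all(abs(cy$alive + cumsum(cy$deaths) - 1) < 1e-10),
                label = s$id)
    expect_true(all(cy$alive >= 0))
  }
})

test_that("a zero-cycle horizon returns the initial occupancy only", {
  p <- apply_override(base_params, "config.horizon", "fixed")
  p <- apply_override(p, "config.horizon_years", 0)
  tr <- run_trace(strategy_denosumab(), p)
  expect_equal(nrow(tr$cycles), 0)
  e <- evaluate_strategy(strategy_denosumab(), p)
  expect_equal(e$cost_total, 0)
  expect_equal(e$qaly, 0)
})

test_that("a neutral treatment reproduces the no-treatment trace", {
  tr_neutral <- run_trace(neutral_denosumab, neutral_params)
  tr_none <- run_trace(strategy_no_treatment(), neutral_params)
  expect_equal(tr_neutral$cycles[-1], tr_none$cycles[-1], tolerance = 1e-12)
})

test_that("with no fractures and no excess, survival is the life-table product", {
  p <- base_params
  p$incidence$rate <- 0
  p <- validate_parameters(p)
  p <- apply_override(p, "config.excess_mortality_attribution", 0)
  tr <- run_trace(strategy_no_treatment(), p)
  fr <- osteomark:::model_frame(strategy_no_treatment(), p)
  expect_equal(tr$cycles$alive, cumprod(1 - fr$q_cycle), tolerance = 1e-12)
  expect_equal(sum(tr$cycles$ev_hip) + sum(tr$cycles$ds_vert), 0)
})

test_that("single-cycle routing matches the exhaustive path computation", {
  # deterministic reduction: no deaths, only hip fractures possible at a
  # known constant rate; expected masses follow by hand
  p <- inert_params
  p$incidence$rate[p$incidence$site == "hip"] <- 0.08
  p <- validate_parameters(p)
  mean72 <- p$rr$mean_pop_tscore$t_score[p$rr$mean_pop_tscore$age == 72]
  p <- apply_override(p, "config.t_score", mean72)       # BMD RR = 1
  p <- apply_override(p, "config.prevalent_vf_fraction", 0)
  tr <- run_trace(strategy_no_treatment(), p, store_compartments = TRUE)
  ph <- 1 - exp(-0.08 * 0.5)
  c0 <- tr$compartments[tr$compartments$cycle == 0, ]
  expect_equal(c0$mass[c0$state == "hip_fx"], ph)
  expect_equal(c0$mass[c0$state == "well"], 1 - ph)
  # cycle 1 by exhaustive paths: acute hip collects re-fractures (at the
  # prior-fracture RR, 1.90 x 0.90 against a BMD RR of 1 under the max
  # rule) plus first fractures out of well; everyone else convalesces.
  ph1 <- 1 - exp(-0.08 * 1.90 * 0.90 * 0.5)
  c1 <- tr$compartments[tr$compartments$cycle == 1, ]
  expect_equal(c1$mass[c1$state == "hip_fx"], ph * ph1 + (1 - ph) * ph,
               tolerance = 1e-12)
  expect_equal(c1$mass[c1$state == "post_hip"], ph * (1 - ph1),
               tolerance = 1e-12)
  expect_equal(c1$mass[c1$state == "well"], (1 - ph)^2, tolerance = 1e-12)
})

test_that("downstream events only arise from occupied hierarchy states", {
  # no vertebral/wrist/other risk => no downstream events despite hip risk
  p <- inert_params
  p$incidence$rate[p$incidence$site == "hip"] <- 0.05
  p <- validate_parameters(p)
  tr <- run_trace(strategy_no_treatment(), p)
  expect_equal(sum(tr$cycles$ds_vert) + sum(tr$cycles$ds_wrist) +
                 sum(tr$cycles$ds_other), 0)
  # and the converse: downstream events are bounded by occupancy times the
  # (untreated, prior-fracture) lower-site cycle probabilities
  set.seed(99)
  for (k in 1:3) {
    pk <- sample_parameters(base_params, 0.10)
    trk <- run_trace(strategy_no_treatment(), pk)
    cy <- trk$cycles
    for (t in seq_len(nrow(cy))) {
      bound <- cy$alive[t] * sum(vapply(
        c("vertebral", "wrist", "other"),
        function(s) cycle_fracture_prob(s, cy$age[t], pk, TRUE, 1), 0))
      expect_lte(cy$ds_vert[t] + cy$ds_wrist[t] + cy$ds_other[t],
                 bound + 1e-12)
    }
  }
})

test_that("treatment cannot increase site-wise fracture burden", {
  tr_tx <- run_trace(strategy_denosumab(), base_params)
  tr_none <- run_trace(strategy_no_treatment(), base_params)
  tot <- function(tr, site) {
    cy <- tr$cycles
    switch(site,
           hip = sum(cy$ev_hip),
           vert = sum(cy$ev_vert) + sum(cy$ds_vert),
           wrist = sum(cy$ev_wrist) + sum(cy$ds_wrist),
           other = sum(cy$ev_other) + sum(cy$ds_other))
  }
  for (site in c("hip", "vert", "wrist", "other")) {
    expect_gte(tot(tr_none, site), tot(tr_tx, site))
  }
})

test_that("trace export writes one row per cycle-compartment", {
  tr <- run_trace(strategy_no_treatment(), base_params,
                  store_compartments = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  export_trace(tr, f)
  out <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(out), nrow(tr$compartments))
  expect_error(export_trace(run_trace(strategy_no_treatment(), base_params),
                            f), "store_compartments")
})
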