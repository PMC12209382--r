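# Risk composition: gradients, prior-fracture RRs, treatment effects,
# offset decay, probability conversion.

test_that("bmd_rr follows the gradient-of-risk power law", {
  p <- base_params
  mean72 <- p$rr$mean_pop_tscore$t_score[p$rr$mean_pop_tscore$age == 72]
  expect_equal(bmd_rr("hip", 72, mean72, p), 1.0)
  expect_equal(bmd_rr("hip", 72, mean72 - 1, p), 2.60)
  # log-linear oracle: two SD below mean
  expect_equal(bmd_rr("vertebral", 72, mean72 - 2, p), exp(2 * log(1.80)))
  expect_equal(bmd_rr("vertebral", 72, mean72 - 2, p), 3.24)
  # age-specific hip gradient switch
  p2 <- apply_override(p, "config.hip_gradient", "age_specific")
  expect_equal(bmd_rr("hip", 72, mean72 - 1, p2), 2.78)
  expect_error(bmd_rr("hip", 20, -2.5, p), "below table support")
})

test_that("prior-fracture RRs: published values, age keying, adjustment", {
  p <- base_params
  expect_equal(prior_fx_rr("vertebral", 72, p), 3.96)
  expect_equal(prior_fx_rr("hip", 72, p, adjusted = FALSE), 1.90)
  expect_equal(prior_fx_rr("hip", 67, p, adjusted = FALSE), 2.28)
  p2 <- apply_override(p, "rr.bmd_adjustment_factor", 1.0)
  expect_equal(prior_fx_rr("wrist", 72, p2), 1.40)
})

test_that("treatment_rr is the documented step function of months on drug", {
  p <- base_params
  expect_equal(treatment_rr(p, "denosumab", "hip", 30), 0.28)
  expect_equal(treatment_rr(p, "denosumab", "hip", 6), 0.55)
  expect_equal(treatment_rr(p, "alendronate", "vertebral", 60), 0.51)
  expect_equal(treatment_rr(p, NA, "hip", 30), 1.0)
  expect_equal(treatment_rr(p, "denosumab", "hip", 0), 1.0)
  expect_equal(treatment_rr(p, "denosumab", "wrist", c(6, 18, 30, 120)),
               c(0.84, 0.79, 0.82, 0.82))
  expect_error(treatment_rr(p, "nosuchdrug", "hip", 12), "efficacy")
})

test_that("residual_rr decays linearly over the dynamic offset", {
  expect_equal(residual_rr(0.5, 60, 12, 2), 0.75)        # midpoint
  expect_equal(residual_rr(0.5, 60, 0, 2), 0.5)           # continuity at stop
  expect_equal(residual_rr(0.5, 60, 24, 2), 1.0)          # full return
  expect_equal(residual_rr(0.5, 60, 240, 2), 1.0)
  expect_equal(residual_rr(0.5, 60, 3, 0), 1.0)           # zero offset
  # early discontinuation shortens the offset: 6 months on => 6-month offset
  expect_equal(residual_rr(0.5, 6, 3, 2), 0.75)
  expect_error(residual_rr(0.5, 60, -1, 2), ">= 0")
  # monotone nondecreasing in time off
  r <- residual_rr(0.3, 36, seq(0, 40, 2), 2)
  expect_true(all(diff(r) >= 0))
  # a vector of per-site r0 with scalar clocks decays site by site
  r4 <- residual_rr(c(0.55, 0.39, 0.84, 0.84), 6, 3, 1)
  expect_equal(r4, c(0.55, 0.39, 0.84, 0.84) +
                 (1 - c(0.55, 0.39, 0.84, 0.84)) * 0.5)
})

test_that("cycle probability composes rate x RRs with exponential conversion", {
  p <- apply_override(base_params, "incidence.hip.72", 0.02)
  expect_equal(cycle_fracture_prob("hip", 72, p, FALSE, treat_rr = 1) > 0, TRUE)
  # with all RRs forced to 1 via t_score at the population mean
  mean72 <- p$rr$mean_pop_tscore$t_score[p$rr$mean_pop_tscore$age == 72]
  p2 <- apply_override(p, "config.t_score", mean72)
  expect_equal(cycle_fracture_prob("hip", 72, p2, FALSE, treat_rr = 1),
               1 - exp(-0.01))
  expect_equal(1 - exp(-0.01), 0.00995, tolerance = 1e-4)
  # zero general-population rate gives zero probability
  p3 <- apply_override(base_params, "incidence.hip.72", 0)
  expect_equal(cycle_fracture_prob("hip", 72, p3, FALSE, treat_rr = 1), 0)
  # a treatment RR of 0.5 halves the composed rate before conversion
  r1 <- -2 * log(1 - cycle_fracture_prob("hip", 72, p2, FALSE, treat_rr = 1))
  r2 <- -2 * log(1 - cycle_fracture_prob("hip", 72, p2, FALSE, treat_rr = 0.5))
  expect_equal(r2, r1 / 2, tolerance = 1e-12)
})

test_that("lowering a treatment RR never raises the cycle probability", {
  p <- base_params
  for (site in c("hip", "vertebral", "wrist", "other")) {
    probs <- vapply(seq(1, 0.1, by = -0.1), function(tr) {
      cycle_fracture_prob(site, 75, p, TRUE, treat_rr = tr)
    }, 0)
    expect_true(all(diff(probs) <= 0))
  }
})

test_that("exponential conversion matches a per-day Bernoulli oracle", {
  days <- 365.25 / 2
  for (rate in seq(0.01, 0.3, by = 0.01)) {
    p_exp <- 1 - exp(-rate * 0.5)
    p_daily <- 1 - (1 - rate / 365.25)^days
    expect_lt(abs(p_exp - p_daily), 1e-4)
  }
})
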