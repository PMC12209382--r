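# Discounting and cost/QALY accrual primitives; accounting identities.

test_that("discount_factor closed forms", {
  expect_equal(discount_factor(0.03, 0), 1.0)
  expect_equal(discount_factor(0, 7), 1.0)
  expect_equal(discount_factor(0.03, 2), 1 / 1.03)
  expect_equal(1 / 1.03, 0.97087, tolerance = 1e-5)
})

test_that("drug and monitoring cycle cost from the unit-cost schedule", {
  p <- base_params
  expect_equal(cycle_drug_and_monitoring_cost(strategy_no_treatment(), p, 1), 0)
  # denosumab: $2899 drug + 2 nurse visits + 1 physician visit + 0.5 DXA,
  # halved per 6-month cycle
  full <- 0.5 * (2899 + 2 * 14.31 + 1 * 90.87 + 0.5 * 38.95)
  expect_equal(cycle_drug_and_monitoring_cost(strategy_denosumab(), p, 1),
               full)
  expect_equal(full, 1518.9825)
  expect_equal(cycle_drug_and_monitoring_cost(strategy_denosumab(), p, 0), 0)
  expect_equal(cycle_drug_and_monitoring_cost(strategy_denosumab(), p, 0.5),
               full / 2)
})

test_that("long-term care cost is expected admission cost per hip event", {
  p <- base_params  # 20% admission, 180-day stay, $216/day
  expect_equal(ltc_cost_accrual(0.01, p), 0.01 * 0.2 * 180 * 216)
  expect_equal(ltc_cost_accrual(0.01, p), 77.76)
  p0 <- apply_override(p, "costs.ltc_admission_prob_after_hip", 0)
  expect_equal(ltc_cost_accrual(0.5, p0), 0)
  expect_equal(ltc_cost_accrual(0, p), 0)
})

test_that("downstream disutility follows the three-step derivation", {
  p <- base_params
  expect_equal(downstream_disutility(0.66, "wrist", 1, p), 0.66 * 0.17)
  expect_equal(0.66 * 0.17, 0.1122)
  expect_equal(downstream_disutility(0.66, "wrist", 0, p), 0)
  p1 <- apply_override(p, "utilities.multiplier.wrist.1", 1)
  expect_equal(downstream_disutility(0.66, "wrist", 1, p1), 0)
})

test_that("utility and fracture-cost lookups select band and year", {
  p <- base_params
  expect_equal(baseline_utility(p, 72), 0.771)
  expect_equal(baseline_utility(p, 83), 0.724)
  expect_equal(utility_multiplier(p, "hip", "1"), 0.550)
  expect_equal(fracture_cost(p, "hip", "1", 72), 51760)
  expect_equal(fracture_cost(p, "hip", "1", 60), 67115)
  expect_equal(fracture_cost(p, "vertebral", "2plus", 72), 5943)
  expect_error(fracture_cost(p, "wrist", "2plus", 72), "no fracture cost")
})

test_that("discounting bounds: discounted <= undiscounted, equal at rate 0", {
  tr <- run_trace(strategy_denosumab(), base_params)
  cy <- tr$cycles
  expect_lte(sum(cy$cost_hip), sum(cy$cost_hip_u))
  expect_lte(sum(cy$cost_drug), sum(cy$cost_drug_u))
  expect_lte(sum(cy$qaly), sum(cy$qaly_u))
  expect_lte(sum(cy$ly), sum(cy$ly_u))
  p0 <- apply_override(base_params, "config.discount_rate_annual", 0)
  cy0 <- run_trace(strategy_denosumab(), p0)$cycles
  expect_equal(sum(cy0$qaly), sum(cy0$qaly_u))
  expect_equal(sum(cy0$cost_hip), sum(cy0$cost_hip_u))
})

test_that("QALYs never exceed life-years", {
  for (s in list(strategy_denosumab(), strategy_alendronate(),
                 strategy_no_treatment())) {
    e <- evaluate_strategy(s, base_params)
    expect_lte(e$qaly, e$ly)
    expect_lte(e$qaly_undisc, e$ly_undisc)
  }
})

test_that("with everything but drug cost zeroed, total cost is drug cost", {
  p <- base_params
  p$costs$fracture$cost <- 0
  p$costs$unit[] <- 0
  p <- apply_override(p, "costs.ltc_admission_prob_after_hip", 0,
                      validate = FALSE)
  p <- validate_parameters(p)
  e <- evaluate_strategy(strategy_denosumab(), p)
  expect_equal(e$cost_total, e$cost_drug)
  expect_gt(e$cost_drug, 0)
})
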