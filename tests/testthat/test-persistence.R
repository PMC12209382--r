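# Persistence curves, extrapolation, cycle timing, discontinuation flows.

test_that("persistence_at returns observed step values in the data window", {
  cv <- persistence_curve(base_params, "denosumab")
  expect_equal(persistence_at(cv, 0), 1.0)
  expect_equal(persistence_at(cv, 6), 0.936)
  expect_equal(persistence_at(cv, 36), 0.380)
  expect_equal(persistence_at(cv, 3), 1.0)       # step: interval start
  expect_error(persistence_at(cv, -1), ">= 0")
})

test_that("extrapolation methods agree on the data window and are valid", {
  for (drug in c("denosumab", "alendronate")) {
    obs <- base_params$persistence[base_params$persistence$drug == drug, ]
    curves <- lapply(c("last_value", "last_interval_rate", "overall_rate"),
                     function(m) persistence_curve(base_params, drug, m))
    for (cv in curves) {
      expect_equal(persistence_at(cv, obs$month), obs$p)
      long <- persistence_at(cv, seq(0, 240, by = 6))
      expect_true(all(diff(long) <= 1e-12))
      expect_true(all(long >= 0 & long <= 1))
    }
  }
})

test_that("overall-rate ratio matches the closed form from the 36-month value", {
  cv <- persistence_curve(base_params, "alendronate", "overall_rate")
  ratio <- 0.172^(1 / 6)
  expect_equal(ratio, 0.7457411, tolerance = 1e-6)
  expect_equal(persistence_at(cv, 42), 0.172 * ratio, tolerance = 1e-12)
  expect_equal(persistence_at(cv, 54), 0.172 * ratio^3, tolerance = 1e-12)
})

test_that("cycle timing conventions: start-of-cycle vs interpolated midpoint", {
  den <- strategy_denosumab()
  alen <- strategy_alendronate()
  sd_ <- strategy_schedule(den, 20)
  sa <- strategy_schedule(alen, 20)
  cvd <- persistence_curve(base_params, "denosumab")
  cva <- persistence_curve(base_params, "alendronate")
  expect_equal(cycle_persistent_fraction(cvd, den, sd_, 0), 1.0)
  expect_equal(cycle_persistent_fraction(cvd, den, sd_, 1), 0.936)
  # alendronate cycle 0: month 3, midway between 1.0 and 0.561
  expect_equal(cycle_persistent_fraction(cva, alen, sa, 0), (1 + 0.561) / 2)
  # holiday cycles: no one newly persistent
  expect_equal(cycle_persistent_fraction(cva, alen, sa, 10), 0)

  flat <- list(drug = "x", month = seq(0, 36, 6), p = rep(1, 7),
               extrapolation = "last_value")
  expect_equal(cycle_persistent_fraction(flat, den, sd_, 3), 1.0)
  expect_equal(cycle_persistent_fraction(flat, alen, sa, 3), 1.0)
})

test_that("discontinuation flows telescope to one", {
  den <- strategy_denosumab()
  sched <- strategy_schedule(den, 20)
  cv <- persistence_curve(base_params, "denosumab")
  fl <- discontinuation_flow(cv, den, sched)
  expect_equal(fl$flow[fl$cycle == 2], 0.936 - 0.727)
  expect_true(all(fl$flow >= 0))
  expect_equal(sum(fl$flow) + fl$persistent[nrow(fl)], 1)

  flat <- list(drug = "x", month = seq(0, 36, 6), p = rep(1, 7),
               extrapolation = "last_value")
  expect_true(all(discontinuation_flow(flat, den, sched)$flow == 0))
})
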