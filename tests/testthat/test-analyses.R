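# Result surfaces: CE analysis, ICER classification, scenarios, OWSA, PSA.

test_that("icer arithmetic and dominance classification", {
  expect_equal(icer(1000, 0.01)$icer, 100000)
  expect_equal(icer(-500, 0.05)$status, "dominant")
  expect_equal(icer(500, -0.05)$status, "dominated")
  expect_equal(icer(0, 0)$status, "indifferent")
  expect_equal(icer(100, 0)$status, "costlier_equal")
  expect_true(is.na(icer(100, 0)$icer))
  expect_equal(icer(-100, -0.01)$status, "cost_saving_less_effective")
})

test_that("evaluate_strategy is deterministic and neutral-equivalent", {
  e1 <- evaluate_strategy(strategy_denosumab(), base_params)
  e2 <- evaluate_strategy(strategy_denosumab(), base_params)
  expect_identical(e1[-1], e2[-1])
  en <- evaluate_strategy(neutral_denosumab, neutral_params)
  e0 <- evaluate_strategy(strategy_no_treatment(), neutral_params)
  expect_equal(as.numeric(en[-1]), as.numeric(e0[-1]), tolerance = 1e-12)
})

test_that("ce_analysis produces consistent incrementals and tidiers", {
  ce <- ce_analysis(base_params)
  expect_s3_class(ce, "osteo_ce")
  inc <- ce$incremental
  res <- ce$results
  den <- res[res$strategy == "denosumab_10y", ]
  alen <- res[grepl("^alendronate", res$strategy), ]
  row <- inc[grepl("^alendronate", inc$comparator), ]
  expect_equal(row$delta_cost, den$cost_total - alen$cost_total)
  expect_equal(row$delta_qaly, den$qaly - alen$qaly)
  expect_equal(row$icer, row$delta_cost / row$delta_qaly)
  # category sums reproduce the totals
  cats <- c("cost_drug", "cost_mgmt", "cost_hip", "cost_vert", "cost_wrist",
            "cost_other", "cost_ltc")
  expect_equal(rowSums(res[, cats]), res$cost_total)
  td <- tidy(ce)
  expect_true(all(c("strategy", "icer", "status") %in% names(td)))
  gl <- glance(ce)
  expect_equal(gl$n_comparators, 2L)
})

test_that("net-benefit ranking agrees with the ICER classification", {
  ce <- ce_analysis(base_params)
  row <- ce$incremental[grepl("^alendronate", ce$incremental$comparator), ]
  expect_equal(row$status, "icer")
  nb <- function(lambda) lambda * row$delta_qaly - row$delta_cost
  expect_lt(nb(row$icer * 0.9), 0)
  expect_gt(nb(row$icer * 1.1), 0)
  expect_equal(nb(row$icer), 0, tolerance = 1e-6)
})

test_that("scenario grid reproduces the base case and orders holidays", {
  grid <- tibble::tibble(on1 = c(5, 5, 5, 5), holiday = c(2, 1, 3, 0),
                         on2 = c(3, 4, 2, 0), den_years = c(10, 10, 10, 5))
  sg <- scenario_grid(base_params, grid)
  base_icer <- ce_analysis(base_params)$incremental
  base_icer <- base_icer$icer[grepl("^alendronate", base_icer$comparator)]
  expect_equal(sg$icer[sg$holiday == 2 & sg$den_years == 10], base_icer)
  # longer holiday (same on-time window) lowers the ICER
  expect_lt(sg$icer[sg$holiday == 3], sg$icer[sg$holiday == 2])
  expect_gt(sg$icer[sg$holiday == 1], sg$icer[sg$holiday == 2])
  # the 5y-vs-5y special case is present and finite
  expect_true(is.finite(sg$icer[sg$den_years == 5]))
})

test_that("owsa: identity variant reproduces base case; unknown paths error", {
  tab <- owsa(base_params, list(
    list(label = "identity",
         overrides = list("config.discount_rate_annual" = 0.03))
  ))
  expect_equal(tab$icer_vs_alen[tab$label == "identity"],
               tab$icer_vs_alen[tab$label == "base_case"])
  expect_error(owsa(base_params, list(
    list(label = "bad", overrides = list("config.nonsense" = 1))
  )), "unknown")
})

test_that("psa is seed-reproducible and degenerates to the base case", {
  p1 <- psa(base_params, n = 4, seed = 11, se_fraction = 0.1)
  p2 <- psa(base_params, n = 4, seed = 11, se_fraction = 0.1)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ceac, p2$ceac)
  # zero-variance single draw equals the deterministic evaluation
  p0 <- psa(base_params, n = 1, seed = 5, se_fraction = 0)
  det <- ce_analysis(base_params)$results
  for (s in det$strategy) {
    expect_equal(p0$draws$cost[p0$draws$strategy == s],
                 det$cost_total[det$strategy == s], tolerance = 1e-12)
    expect_equal(p0$draws$qaly[p0$draws$strategy == s],
                 det$qaly[det$strategy == s], tolerance = 1e-12)
  }
  expect_true(all(p0$ceac$prob %in% c(0, 1)))
})

test_that("sampled parameter sets respect the container invariants", {
  set.seed(21)
  for (k in 1:5) {
    pk <- sample_parameters(base_params, 0.1)
    expect_s3_class(pk, "osteo_params")   # validate_parameters passed
    for (d in unique(pk$persistence$drug)) {
      pp <- pk$persistence[pk$persistence$drug == d, ]
      expect_true(all(diff(pp$p[order(pp$month)]) <= 0))
    }
  }
  expect_warning(osteomark:::.beta_draw(1, 0.5, 10), "clipped")
})

test_that("plot methods return ggplot objects", {
  ps <- psa(base_params, n = 3, seed = 2)
  expect_s3_class(ggplot2::autoplot(ps), "ggplot")
  expect_s3_class(plot_ceac(ps), "ggplot")
  tr <- run_trace(strategy_no_treatment(), base_params)
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
})
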