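# Parameter container: defaults, validation, overrides, serialization.

test_that("bundled defaults carry the published input values", {
  p <- base_params
  expect_equal(unname(p$rr$per_sd), c(2.60, 1.80, 1.40, 1.60))
  expect_equal(p$efficacy$rr[p$efficacy$drug == "denosumab" &
                               p$efficacy$site == "hip" &
                               p$efficacy$months == 36], 0.28)
  expect_equal(p$persistence$p[p$persistence$drug == "denosumab" &
                                 p$persistence$month == 6], 0.936)
  expect_equal(p$costs$unit[["dxa"]], 38.95)
  expect_equal(p$utilities$baseline$utility[p$utilities$baseline$age == 70],
               0.771)
  expect_equal(p$costs$ltc_per_day, 216)
})

test_that("adjusted prior-fracture RRs are 0.90 x originals to 3 sig figs", {
  p <- base_params
  for (case in list(list("vertebral", 3.96), list("wrist", 1.26),
                    list("other", 1.71))) {
    adj <- prior_fx_rr(case[[1]], 72, p, adjusted = TRUE)
    orig <- prior_fx_rr(case[[1]], 72, p, adjusted = FALSE)
    expect_equal(signif(orig * 0.90, 3), case[[2]])
    expect_equal(adj, orig * 0.90)
  }
})

test_that("validation rejects invariant violations naming the field", {
  p <- base_params
  bad <- p
  bad$persistence$p[bad$persistence$drug == "denosumab" &
                      bad$persistence$month == 0] <- 0.8
  expect_error(validate_parameters(bad), "persistence.denosumab.0",
               fixed = TRUE)

  bad <- p
  bad$costs$fracture$cost[1] <- -5
  expect_error(validate_parameters(bad), "costs.fracture.cost")

  bad <- p
  bad$utilities$baseline$utility[1] <- 1.2
  expect_error(validate_parameters(bad), "utilities.baseline.utility")

  bad <- p
  bad$config$cycle_length <- 1
  expect_error(validate_parameters(bad), "cycle_length")
})

test_that("apply_override changes exactly the addressed field", {
  p <- base_params
  p2 <- apply_override(p, "config.discount_rate_annual", 0.05)
  expect_equal(p2$config$discount_rate_annual, 0.05)
  expect_equal(p$config$discount_rate_annual, 0.03)  # original untouched
  p2$config$discount_rate_annual <- 0.03
  expect_equal(unclass(p2), unclass(p))

  p3 <- apply_override(p, "config.start_age", 65L)
  expect_equal(p3$config$start_age, 65L)

  p4 <- apply_override(p, "rr.per_sd.hip", 2.89)
  expect_equal(p4$rr$per_sd[["hip"]], 2.89)

  p5 <- apply_override(p, "efficacy.denosumab.hip.12", 0.6)
  expect_equal(p5$efficacy$rr[p5$efficacy$drug == "denosumab" &
                                p5$efficacy$site == "hip" &
                                p5$efficacy$months == 12], 0.6)
})

test_that("unknown override paths error with suggestions", {
  expect_error(apply_override(base_params, "foo.bar", 1), "unknown")
  expect_error(apply_override(base_params, "config.discount_rate", 1),
               "discount_rate_annual")
  expect_error(apply_override(base_params, "efficacy.denosumab.hip", 0.5),
               "does not address a cell")
})

test_that("bundle serialization round-trips losslessly and layers defaults", {
  dir <- withr::local_tempdir()
  write_bundle(base_params, dir)
  p2 <- load_parameters(dir)
  expect_equal(unclass(p2), unclass(base_params), tolerance = 1e-12)

  # defaults with no bundle are the default set
  expect_equal(unclass(load_parameters(NULL)), unclass(base_params))

  # a manifest pointing at a missing table file names the table
  file.remove(file.path(dir, "efficacy.csv"))
  expect_error(load_parameters(dir), "efficacy")
})

test_that("generated bundles are seed-deterministic byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_bundle(42, d1)
  gen_bundle(42, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  p <- load_parameters(d1)
  expect_s3_class(p, "osteo_params")
})
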