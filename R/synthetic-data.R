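# Synthetic stand-ins for inputs the primary sources do not print.
#
# These are documented assumptions with the statistical structure the model
# expects (Gompertz-Makeham mortality, exponential-in-age fracture
# incidence, linear decline in population mean T-score), calibrated to
# order-of-magnitude realism: female life expectancy at 72 of ~15-17 years
# and an untreated base-case lifetime fracture burden of order one event per
# patient. They carry no claim of epidemiological accuracy and are replaced
# wholesale when measured tables are supplied in a bundle.

#' Synthetic female period life table
#'
#' Annual all-cause death probabilities `q(x)` for women aged 50-110 from a
#' Gompertz-Makeham law `q(x) = min(1, a + b exp(c x))` with
#' `a = 3e-4`, `b = 2e-5`, `c = 0.094`, forced to 1 at the terminal age.
#' The parameters put life expectancy at age 72 in the 15-17 year range and
#' make `q` nondecreasing beyond age 60.
#'
#' @param seed integer; generation is deterministic given the seed (the
#'   default law has no random component, the argument fixes the interface).
#' @param max_age terminal age (default 110).
#' @return tibble with columns `age`, `q`.
#' @export
#' @examples
#' lt <- gen_life_table(1)
#' lt$q[lt$age == 110]
gen_life_table <- function(seed = 1L, max_age = 110L) {
  age <- seq(50L, max_age)
  q <- pmin(1, 3e-4 + 2e-5 * exp(0.094 * age))
  q[age == max_age] <- 1
  tibble::tibble(age = age, q = q)
}

#' Synthetic post-fracture excess-mortality relative risks
#'
#' Age-keyed relative risks of all-cause mortality following hip, vertebral
#' and other fractures, declining with age as observed in registry studies
#' (the relative excess shrinks as baseline mortality grows). Wrist
#' fractures carry no excess mortality.
#'
#' @inheritParams gen_life_table
#' @return tibble with columns `site`, `age`, `rr`.
#' @export
gen_post_fracture_mortality_rr <- function(seed = 1L) {
  tibble::tibble(
    site = rep(c("hip", "vertebral", "other"), each = 5L),
    age = rep(c(50, 60, 70, 80, 90), 3L),
    rr = c(
      4.0, 3.4, 3.0, 2.2, 1.8,   # hip
      2.6, 2.2, 2.0, 1.7, 1.4,   # vertebral
      1.7, 1.6, 1.5, 1.3, 1.2    # other
    )
  )
}

#' Synthetic general-population fracture incidence
#'
#' Site-specific fracture rates per person-year for women, exponential in
#' age: `rate(age) = r70 * exp(k (age - 70))`. Hip incidence rises about
#' 10-fold from 55 to 85 (`k = ln(10)/30`), vertebral comparably, wrist
#' nearly flat. Anchors at age 70 are scaled so the untreated base-case
#' cohort accumulates on the order of one fracture per patient over a
#' lifetime.
#'
#' @inheritParams gen_life_table
#' @return tibble with columns `site`, `age`, `rate`.
#' @export
gen_incidence_table <- function(seed = 1L, max_age = 110L) {
  age <- seq(50L, max_age)
  anchors <- c(hip = 0.0040, vertebral = 0.0045, wrist = 0.0120,
               other = 0.0100)
  slopes <- c(hip = log(10) / 30, vertebral = 0.055, wrist = 0.012,
              other = 0.025)
  purrr::map_dfr(names(anchors), function(s) {
    tibble::tibble(site = s, age = age,
                   rate = anchors[[s]] * exp(slopes[[s]] * (age - 70)))
  })
}

#' Synthetic population mean T-score by age
#'
#' Mean femoral-neck T-score for women declining linearly with age,
#' -0.9 SD at 65 to -1.8 SD at 85 (slope -0.045 SD/year), extended linearly
#' over 50-110. The modeled patient (T = -2.5) sits below the population
#' mean at all ages up to 85, so the BMD relative risk exceeds 1 there.
#'
#' @inheritParams gen_life_table
#' @return tibble with columns `age`, `t_score`.
#' @export
gen_population_tscore <- function(seed = 1L, max_age = 110L) {
  age <- seq(50L, max_age)
  tibble::tibble(age = age, t_score = -0.9 - 0.045 * (age - 65))
}

#' Generate a complete parameter bundle on disk
#'
#' Writes the published default inputs verbatim together with the synthetic
#' stand-ins above as a bundle directory that [load_parameters()] accepts.
#' Byte-identical across runs with the same seed.
#'
#' @param seed integer seed for the synthetic tables.
#' @param out_dir directory to write.
#' @return `out_dir`, invisibly.
#' @export
gen_bundle <- function(seed, out_dir) {
  write_bundle(default_parameters(synthetic_seed = seed), out_dir)
}
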