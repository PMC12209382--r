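# Risk composition: per-cycle, per-site fracture probability as
# (general-population rate) x (disease relative risk) x (treatment effect),
# converted to a 6-month probability by exponential conversion.

#' BMD-related relative risk of fracture
#'
#' The gradient-of-risk model: `rr_per_sd(site)` raised to the number of
#' standard deviations the patient's T-score lies below the age-specific
#' population mean. For hip fractures the age-keyed gradient replaces the
#' pooled value when `config$hip_gradient = "age_specific"`.
#'
#' @param site fracture site.
#' @param age patient age in years.
#' @param t_score patient T-score (SD).
#' @param params an `osteo_params` object.
#' @return relative risk (>= 0).
#' @export
#' @examples
#' p <- default_parameters()
#' bmd_rr("vertebral", 72, -2.5, p)
bmd_rr <- function(site, age, t_score, params) {
  stopifnot(site %in% .SITES)
  g <- params$rr$per_sd[[site]]
  if (site == "hip" && identical(params$config$hip_gradient, "age_specific")) {
    tab <- params$rr$hip_per_sd_by_age
    g <- age_lookup(tab$age, tab$rr, age, params$config$age_lookup)
  }
  ts <- params$rr$mean_pop_tscore
  mean_t <- age_lookup(ts$age, ts$t_score, age, params$config$age_lookup)
  g^(mean_t - t_score)
}

#' Prior-fracture relative risk
#'
#' Published relative risks of fracture at `site` for patients with a
#' history of prior fracture; the hip value is age-keyed. When `adjusted`,
#' values are scaled down by the BMD adjustment factor (0.90) to avoid
#' double counting the BMD-related risk.
#'
#' @inheritParams bmd_rr
#' @param adjusted apply the downward BMD adjustment (default `TRUE`).
#' @export
#' @examples
#' prior_fx_rr("vertebral", 72, default_parameters())  # 4.40 x 0.90 = 3.96
prior_fx_rr <- function(site, age, params, adjusted = TRUE) {
  stopifnot(site %in% .SITES)
  tab <- params$rr$prior_fx[params$rr$prior_fx$site == site, ]
  if (nrow(tab) == 1L && is.na(tab$age)) {
    base <- tab$rr
  } else {
    base <- age_lookup(tab$age, tab$rr, age, params$config$age_lookup)
  }
  if (adjusted) base * params$rr$bmd_adjustment_factor else base
}

#' Treatment relative risk while on treatment
#'
#' Step function of cumulative months on treatment: the 12-month RR applies
#' through the first year, the 24-month RR through the second, and the
#' 36-month RR from the third year onward (efficacy is carried forward at
#' the 36-month value). Zero months on treatment means no effect (RR 1).
#'
#' @param params an `osteo_params` object.
#' @param drug drug identifier, or `NA` for no treatment.
#' @param site fracture site.
#' @param months_on cumulative months on treatment (vectorized, >= 0).
#' @export
#' @examples
#' treatment_rr(default_parameters(), "denosumab", "hip", 30)  # 0.28
treatment_rr <- function(params, drug, site, months_on) {
  if (any(months_on < 0)) stop("months_on must be >= 0", call. = FALSE)
  if (is.na(drug)) return(rep(1, length(months_on)))
  tab <- params$efficacy[params$efficacy$drug == drug &
                           params$efficacy$site == site, ]
  if (nrow(tab) == 0L) stop("no efficacy data for drug `", drug, "`",
                            call. = FALSE)
  rr_at <- stats::setNames(tab$rr, tab$months)
  ifelse(months_on <= 0, 1,
         ifelse(months_on <= 12, rr_at[["12"]],
                ifelse(months_on <= 24, rr_at[["24"]], rr_at[["36"]])))
}

#' Residual treatment effect after discontinuation
#'
#' After stopping, the treatment RR returns linearly from its value at
#' discontinuation (`r0`) to 1 over the effective offset time, which is the
#' smaller of time spent on treatment and the drug's maximum offset (the
#' "dynamic" offset: early discontinuers get a shorter residual benefit).
#'
#' @param r0 RR at the moment of discontinuation.
#' @param months_on_at_disc months on treatment when stopping.
#' @param months_since_off months since stopping (vectorized, >= 0).
#' @param max_offset_years drug's maximum offset time in years.
#' @return RR in `[r0, 1]`; exactly 1 once the offset has elapsed, and
#'   immediately 1 when the effective offset is zero.
#' @export
#' @examples
#' residual_rr(0.5, 60, 12, 2)  # halfway through a 24-month offset: 0.75
residual_rr <- function(r0, months_on_at_disc, months_since_off,
                        max_offset_years) {
  if (any(months_since_off < 0) || any(months_on_at_disc < 0)) {
    stop("durations must be >= 0", call. = FALSE)
  }
  len <- max(length(r0), length(months_on_at_disc), length(months_since_off))
  r0 <- rep_len(r0, len)
  mo <- rep_len(months_on_at_disc, len)
  mso <- rep_len(months_since_off, len)
  T_eff <- pmin(mo, 12 * max_offset_years)
  out <- r0 + (1 - r0) * pmin(mso / pmax(T_eff, 1e-12), 1)
  out[T_eff <= 0] <- 1
  out
}

#' Per-cycle fracture probability
#'
#' Composes the annual rate
#' `gen_pop_rate(site, age) x disease RR x treatment RR` and converts it to
#' a 6-month probability via `1 - exp(-rate/2)`. The disease RR is the BMD
#' gradient for patients without prior fracture; for patients with a prior
#' fracture the default rule takes the larger of the BMD gradient and the
#' adjusted prior-fracture RR (`config$disease_rr_rule = "max"`), with a
#' `"multiply"` alternative that treats the 10% downward adjustment as
#' licence to combine the two.
#'
#' @inheritParams bmd_rr
#' @param has_prior_fx logical: history of any fracture.
#' @param treat_rr treatment (or residual) relative risk in force this
#'   cycle; 1 for untreated.
#' @return probability in \[0, 1).
#' @export
#' @examples
#' p <- default_parameters()
#' cycle_fracture_prob("hip", 72, p, has_prior_fx = FALSE, treat_rr = 1)
cycle_fracture_prob <- function(site, age, params, has_prior_fx = FALSE,
                                treat_rr = 1) {
  inc <- params$incidence[params$incidence$site == site, ]
  g <- age_lookup(inc$age, inc$rate, age, params$config$age_lookup)
  dis <- disease_rr(site, age, params, has_prior_fx)
  rate <- g * dis * treat_rr
  stopifnot(rate >= 0)
  1 - exp(-rate * params$config$cycle_length)
}

#' @rdname cycle_fracture_prob
#' @export
disease_rr <- function(site, age, params, has_prior_fx) {
  b <- bmd_rr(site, age, params$config$t_score, params)
  if (!has_prior_fx) return(b)
  pf <- prior_fx_rr(site, age, params, adjusted = TRUE)
  switch(params$config$disease_rr_rule,
         max = max(b, pf),
         multiply = b * pf,
         stop("unknown disease_rr_rule", call. = FALSE))
}
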