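# Economic accrual primitives. The cohort and microsimulation engines share
# these; per-compartment accrual itself lives in the cycle loops.

#' Discount factor at a cycle index
#'
#' `(1 + rate)^(-cycle * 0.5)`: cycle indices are 6-month steps. The engines
#' discount each cycle's accrual at the cycle end by default
#' (`config$discount_timing = "end"`), i.e. with `discount_factor(r, t + 1)`
#' for 0-based cycle `t`; `"start"` and `"mid"` are available.
#'
#' @param rate_annual annual discount rate (>= 0).
#' @param cycle_index cycle index (vectorized).
#' @export
#' @examples
#' discount_factor(0.03, 2)  # one year out: 1/1.03
discount_factor <- function(rate_annual, cycle_index) {
  stopifnot(rate_annual >= 0)
  (1 + rate_annual)^(-cycle_index * 0.5)
}

#' Drug and monitoring cost for one cycle
#'
#' Half a year of drug acquisition plus monitoring/administration (nurse
#' visits, physician visits, DXA scans at their unit costs), scaled by the
#' fraction of the cohort persistent on drug. Zero during holidays and for
#' no treatment (persistent fraction 0).
#'
#' @param strat an `osteo_strategy`.
#' @param params an `osteo_params` object (unit costs).
#' @param persistent_fraction proportion on drug during the cycle.
#' @return USD per cycle per unit cohort mass.
#' @export
#' @examples
#' cycle_drug_and_monitoring_cost(strategy_denosumab(), default_parameters(), 1)
cycle_drug_and_monitoring_cost <- function(strat, params, persistent_fraction) {
  stopifnot(persistent_fraction >= 0, persistent_fraction <= 1)
  u <- params$costs$unit
  annual <- strat$annual_drug_cost +
    strat$nurse_visits_per_year * u[["nurse_visit"]] +
    strat$physician_visits_per_year * u[["physician_visit"]] +
    strat$dxa_per_year * u[["dxa"]]
  persistent_fraction * 0.5 * annual
}

#' Fracture treatment cost lookup
#'
#' Year-1 or year-2+ cost for a site and age band; wrist and other
#' fractures have year-1 costs only (no chronic state).
#'
#' @param params an `osteo_params` object.
#' @param site fracture site.
#' @param year `"1"` or `"2plus"`.
#' @param age cohort age (selects the 50-64 vs 65+ band).
#' @export
fracture_cost <- function(params, site, year, age) {
  band <- if (age >= 65) "65plus" else "50_64"
  tab <- params$costs$fracture
  hit <- tab$cost[tab$site == site & tab$year == year & tab$age_band == band]
  if (length(hit) != 1L) {
    stop(sprintf("no fracture cost for site=%s year=%s band=%s",
                 site, year, band), call. = FALSE)
  }
  hit
}

#' Expected long-term care cost per hip fracture event
#'
#' Nursing-home costs apply only to patients entering long-term care after a
#' hip fracture: admission probability times mean stay times the per-day
#' cost, delivered as a one-time expected cost at the event.
#'
#' @param hip_events hip fracture events this cycle (>= 0).
#' @param params an `osteo_params` object.
#' @export
#' @examples
#' # 0.01 events, 20% admission, 180-day stay at $216/day
#' ltc_cost_accrual(0.01, default_parameters())
ltc_cost_accrual <- function(hip_events, params) {
  stopifnot(all(hip_events >= 0))
  hip_events * params$costs$ltc_admission_prob_after_hip *
    params$costs$ltc_mean_stay_days * params$costs$ltc_per_day
}

#' Baseline utility at an age
#'
#' Age-band utility for women in the general population (50s, 60s, 70s,
#' 80+).
#'
#' @param params an `osteo_params` object.
#' @param age age in years.
#' @export
baseline_utility <- function(params, age) {
  tab <- params$utilities$baseline
  age_lookup(tab$age, tab$utility, age, "step")
}

#' Utility multiplier for a fracture state
#'
#' @param params an `osteo_params` object.
#' @param site fracture site.
#' @param year `"1"` (acute, two cycles) or `"2plus"` (chronic hip/vertebral
#'   states).
#' @export
utility_multiplier <- function(params, site, year) {
  tab <- params$utilities$multiplier
  hit <- tab$mult[tab$site == site & tab$year == year]
  if (length(hit) != 1L) {
    stop(sprintf("no utility multiplier for site=%s year=%s", site, year),
         call. = FALSE)
  }
  hit
}

#' QALY decrement of a downstream fracture
#'
#' A lower-hierarchy fracture sustained while occupying a higher-hierarchy
#' state does not change state; its acute utility loss is the difference
#' between the occupied state's utility and that utility times the lower
#' site's year-1 multiplier, applied over the one-year acute window.
#'
#' @param higher_utility utility of the occupied higher-hierarchy state
#'   (baseline utility times its multiplier).
#' @param lower_site site of the downstream fracture.
#' @param events number of downstream events.
#' @param params an `osteo_params` object.
#' @param years duration over which the acute decrement applies (default 1).
#' @return QALYs lost (>= 0).
#' @export
#' @examples
#' downstream_disutility(0.66, "wrist", 1, default_parameters())  # 0.1122
downstream_disutility <- function(higher_utility, lower_site, events, params,
                                  years = 1) {
  stopifnot(all(events >= 0), higher_utility > 0, higher_utility <= 1)
  m <- utility_multiplier(params, lower_site, "1")
  events * higher_utility * (1 - m) * years
}
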