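# Treatment persistence: observed 36-month curves, long-term extrapolation,
# cycle-timing conventions and discontinuation flows.

#' Persistence curve for a drug
#'
#' Packages the observed 6-monthly persistence proportions for `drug`
#' together with the configured long-term extrapolation method into the
#' curve object the persistence operations consume.
#'
#' @param params an `osteo_params` object.
#' @param drug drug identifier.
#' @param extrapolation one of `"last_value"`, `"last_interval_rate"`,
#'   `"overall_rate"`; defaults to the config setting.
#' @return a list with elements `drug`, `month`, `p`, `extrapolation`.
#' @export
persistence_curve <- function(params, drug,
                              extrapolation = params$config$persistence_extrapolation) {
  tab <- params$persistence[params$persistence$drug == drug, ]
  if (nrow(tab) == 0L) stop("no persistence data for drug `", drug, "`",
                            call. = FALSE)
  tab <- tab[order(tab$month), ]
  stopifnot(extrapolation %in% c("last_value", "last_interval_rate",
                                 "overall_rate"))
  list(drug = drug, month = tab$month, p = tab$p,
       extrapolation = extrapolation)
}

# Per-6-month retention ratio used beyond the observation window.
.extrap_ratio <- function(curve) {
  n <- length(curve$p)
  switch(curve$extrapolation,
    # "last value": hold the final interval's retention ratio constant.
    # On 6-monthly data this coincides with "last interval rate"; both are
    # offered because sensitivity analyses list them as distinct options.
    last_value = ,
    last_interval_rate = curve$p[n] / curve$p[n - 1L],
    overall_rate = curve$p[n]^(1 / (n - 1L))
  )
}

#' Persistence at a given month
#'
#' Within the observation window returns the observed step value for the
#' containing 6-month interval (or the linear interpolation between adjacent
#' observations when `interpolate = TRUE`, the rule used for midpoint-timed
#' drugs). Beyond the window the configured extrapolation applies: the
#' final-interval retention ratio (`last_value`/`last_interval_rate`) or the
#' constant ratio implied by the 36-month value (`overall_rate`), compounded
#' per 6 months.
#'
#' @param curve a [persistence_curve()].
#' @param month months since treatment start (vectorized, must be >= 0).
#' @param interpolate linearly interpolate between observations.
#' @return proportion(s) persistent in \[0, 1\].
#' @export
#' @examples
#' p <- default_parameters()
#' cv <- persistence_curve(p, "denosumab")
#' persistence_at(cv, c(0, 6, 36, 48))
persistence_at <- function(curve, month, interpolate = FALSE) {
  if (any(month < 0)) stop("month must be >= 0", call. = FALSE)
  last_m <- max(curve$month)
  ratio <- .extrap_ratio(curve)
  eval_grid <- function(m) {
    # persistence on the 6-month grid, extended geometrically beyond data
    within <- m <= last_m
    out <- numeric(length(m))
    out[within] <- curve$p[findInterval(m[within], curve$month)]
    k <- (m[!within] - last_m) / 6
    out[!within] <- curve$p[length(curve$p)] * ratio^k
    out
  }
  if (!interpolate) {
    # step at the containing interval; beyond data compound per whole interval
    m_step <- ifelse(month <= last_m, month, last_m + 6 * floor((month - last_m) / 6))
    return(pmin(1, pmax(0, eval_grid(m_step))))
  }
  lo <- 6 * floor(month / 6)
  hi <- lo + 6
  p_lo <- eval_grid(lo)
  p_hi <- eval_grid(hi)
  w <- (month - lo) / 6
  pmin(1, pmax(0, p_lo + w * (p_hi - p_lo)))
}

#' Persistent fraction applied during a model cycle
#'
#' Denosumab persistence is evaluated at the start of each cycle (aligned
#' with its 6-monthly administration); alendronate at the cycle midpoint,
#' linearly interpolated between adjacent observations. During holiday and
#' post-timeline cycles no one is on drug.
#'
#' @param curve a [persistence_curve()].
#' @param strat an `osteo_strategy` (supplies the timing convention).
#' @param schedule a [strategy_schedule()].
#' @param cycle 0-based cycle index.
#' @return proportion of the cohort on drug during the cycle.
#' @export
cycle_persistent_fraction <- function(curve, strat, schedule, cycle) {
  row <- schedule[schedule$cycle == cycle, ]
  if (nrow(row) != 1L || row$kind != "on") return(0)
  if (strat$persistence_timing == "midpoint") {
    persistence_at(curve, row$months_on_start + 3, interpolate = TRUE)
  } else {
    persistence_at(curve, row$months_on_start, interpolate = FALSE)
  }
}

#' Newly discontinued proportion per cycle
#'
#' The drop in the persistent fraction between consecutive on-treatment
#' cycles. Each flow spawns its own discontinuation stratum carrying the
#' months-on-treatment clock at discontinuation, which fixes both the
#' residual efficacy and the (dynamic) effective offset time.
#'
#' @inheritParams cycle_persistent_fraction
#' @return tibble with one row per cycle: `cycle`, `kind`, `persistent`,
#'   `flow` (newly discontinued), `months_on_at_disc`, `off_ref`
#'   (calendar month at which the off-treatment clock starts).
#' @export
discontinuation_flow <- function(curve, strat, schedule) {
  n <- nrow(schedule)
  persistent <- numeric(n)
  flow <- numeric(n)
  m_disc <- numeric(n)
  off_ref <- numeric(n)
  prev <- 1.0
  mid <- strat$persistence_timing == "midpoint"
  for (i in seq_len(n)) {
    if (schedule$kind[i] == "on") {
      pt <- cycle_persistent_fraction(curve, strat, schedule, schedule$cycle[i])
      persistent[i] <- pt
      flow[i] <- prev - pt
      if (flow[i] < -1e-12) {
        stop("persistence curve increased between cycles; flows must be >= 0",
             call. = FALSE)
      }
      flow[i] <- max(flow[i], 0)
      prev <- pt
    } else {
      persistent[i] <- 0
      flow[i] <- 0
    }
    m_disc[i] <- schedule$months_on_start[i] + if (mid) 3 else 0
    off_ref[i] <- schedule$calendar_start[i] + if (mid) 3 else 0
  }
  tibble::tibble(cycle = schedule$cycle, kind = schedule$kind,
                 persistent = persistent, flow = flow,
                 months_on_at_disc = m_disc, off_ref = off_ref)
}
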