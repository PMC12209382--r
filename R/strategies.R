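# Treatment strategies: a drug plus a timeline of on-treatment / holiday
# segments, offset settings, drug cost and monitoring schedule.

#' Define a treatment strategy
#'
#' A strategy is a drug (or none) with an ordered timeline of on-treatment
#' and drug-holiday segments, a maximum efficacy offset time, an annual drug
#' cost and a monitoring/administration schedule. Segment durations must be
#' multiples of the 6-month cycle.
#'
#' The persistence timing convention follows drug administration: denosumab
#' persistence is evaluated at the start of each cycle (aligned with its
#' 6-monthly injection), oral alendronate at the cycle midpoint.
#'
#' @param id strategy label.
#' @param drug drug identifier matching the efficacy/persistence tables, or
#'   `NA` for no treatment.
#' @param segments tibble with columns `kind` (`"on"`/`"holiday"`) and
#'   `years`.
#' @param max_offset_years maximum linear efficacy offset after
#'   discontinuation, years.
#' @param annual_drug_cost USD per year while persistent.
#' @param nurse_visits_per_year,physician_visits_per_year,dxa_per_year
#'   monitoring/administration schedule while persistent.
#' @param persistence_timing `"cycle_start"` or `"midpoint"`.
#' @return an object of class `osteo_strategy`.
#' @export
#' @examples
#' strategy_denosumab()
#' strategy_alendronate(on1_years = 5, holiday_years = 2, on2_years = 3)
strategy <- function(id, drug, segments, max_offset_years,
                     annual_drug_cost = 0,
                     nurse_visits_per_year = 0,
                     physician_visits_per_year = 0,
                     dxa_per_year = 0,
                     persistence_timing = "cycle_start") {
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) > 0L) {
    stopifnot(all(segments$kind %in% c("on", "holiday")),
              all(abs(segments$years / 0.5 - round(segments$years / 0.5)) < 1e-9),
              all(segments$years > 0))
  }
  structure(
    list(id = id, drug = drug, segments = segments,
         max_offset_years = max_offset_years,
         annual_drug_cost = annual_drug_cost,
         nurse_visits_per_year = nurse_visits_per_year,
         physician_visits_per_year = physician_visits_per_year,
         dxa_per_year = dxa_per_year,
         persistence_timing = persistence_timing),
    class = "osteo_strategy"
  )
}

#' @rdname strategy
#' @param on_years years on denosumab (base case 10).
#' @export
strategy_denosumab <- function(on_years = 10) {
  strategy(
    id = sprintf("denosumab_%gy", on_years), drug = "denosumab",
    segments = tibble::tibble(kind = "on", years = on_years),
    max_offset_years = 1, annual_drug_cost = 2899,
    nurse_visits_per_year = 2, physician_visits_per_year = 1,
    dxa_per_year = 0.5, persistence_timing = "cycle_start"
  )
}

#' @rdname strategy
#' @param on1_years,holiday_years,on2_years alendronate regimen: first
#'   on-treatment block, drug holiday, second on-treatment block (base case
#'   5 + 2 + 3 years).
#' @export
strategy_alendronate <- function(on1_years = 5, holiday_years = 2,
                                 on2_years = 3) {
  seg <- tibble::tibble(
    kind = c("on", "holiday", "on"),
    years = c(on1_years, holiday_years, on2_years)
  )
  seg <- seg[seg$years > 0, ]
  strategy(
    id = sprintf("alendronate_%g_%g_%g", on1_years, holiday_years, on2_years),
    drug = "alendronate", segments = seg,
    max_offset_years = 2, annual_drug_cost = 44,
    nurse_visits_per_year = 0, physician_visits_per_year = 1,
    dxa_per_year = 0.5, persistence_timing = "midpoint"
  )
}

#' @rdname strategy
#' @export
strategy_no_treatment <- function() {
  strategy(id = "no_treatment", drug = NA_character_,
           segments = tibble::tibble(kind = character(), years = numeric()),
           max_offset_years = 0)
}

#' @export
print.osteo_strategy <- function(x, ...) {
  cat("<osteo_strategy>", x$id, "\n")
  if (nrow(x$segments) == 0L) {
    cat("  no treatment\n")
  } else {
    cat(sprintf("  %s: %s; offset <= %g y; $%g/yr\n", x$drug,
                paste(sprintf("%s %gy", x$segments$kind, x$segments$years),
                      collapse = " -> "),
                x$max_offset_years, x$annual_drug_cost))
  }
  invisible(x)
}

#' Per-cycle treatment schedule for a strategy
#'
#' Expands the segment timeline into one row per model cycle: the segment
#' kind in force (`"on"`, `"holiday"`, or `"off"` once the timeline is
#' exhausted), cumulative on-treatment months at the start and end of the
#' cycle (the clock freezes during holidays and after the timeline ends),
#' and calendar months at cycle start.
#'
#' @param strat an `osteo_strategy`.
#' @param n_cycles number of model cycles.
#' @return tibble with columns `cycle`, `kind`, `months_on_start`,
#'   `months_on_end`, `calendar_start`.
#' @export
strategy_schedule <- function(strat, n_cycles) {
  kinds <- rep("off", n_cycles)
  if (nrow(strat$segments) > 0L) {
    per_seg <- rep(strat$segments$kind, times = strat$segments$years * 2L)
    take <- min(length(per_seg), n_cycles)
    kinds[seq_len(take)] <- per_seg[seq_len(take)]
  }
  on_flag <- kinds == "on"
  months_on_end <- cumsum(ifelse(on_flag, 6, 0))
  months_on_start <- c(0, utils::head(months_on_end, -1L))
  tibble::tibble(
    cycle = seq_len(n_cycles) - 1L,
    kind = kinds,
    months_on_start = months_on_start,
    months_on_end = months_on_end,
    calendar_start = 6 * (seq_len(n_cycles) - 1)
  )
}
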