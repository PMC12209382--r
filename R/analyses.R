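# Result surfaces: base-case cost-effectiveness table, scenario grid over
# treatment/holiday durations, one-way sensitivity analysis, probabilistic
# sensitivity analysis with CEACs.

#' Evaluate a strategy
#'
#' Runs the cohort trace and sums the economic accrual into one row:
#' discounted cost by category and in total, cumulative fracture events by
#' site (routed plus downstream adjustments), discounted life-years and
#' QALYs. Deterministic given the inputs.
#'
#' @param strat an `osteo_strategy`.
#' @param params an `osteo_params` object.
#' @return a one-row tibble.
#' @export
#' @examples
#' evaluate_strategy(strategy_no_treatment(), default_parameters())
evaluate_strategy <- function(strat, params) {
  tr <- run_trace(strat, params)
  cy <- tr$cycles
  s <- function(col) if (nrow(cy)) sum(cy[[col]]) else 0
  tibble::tibble(
    strategy = strat$id,
    cost_total = s("cost_drug") + s("cost_mgmt") + s("cost_hip") +
      s("cost_vert") + s("cost_wrist") + s("cost_other") + s("cost_ltc"),
    cost_drug = s("cost_drug"), cost_mgmt = s("cost_mgmt"),
    cost_hip = s("cost_hip"), cost_vert = s("cost_vert"),
    cost_wrist = s("cost_wrist"), cost_other = s("cost_other"),
    cost_ltc = s("cost_ltc"),
    ev_hip = s("ev_hip"),
    ev_vert = s("ev_vert") + s("ds_vert"),
    ev_wrist = s("ev_wrist") + s("ds_wrist"),
    ev_other = s("ev_other") + s("ds_other"),
    ev_any = ev_hip + ev_vert + ev_wrist + ev_other,
    ly = s("ly"), qaly = s("qaly"),
    ly_undisc = s("ly_u"), qaly_undisc = s("qaly_u")
  )
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' @param delta_cost incremental cost (intervention minus comparator), USD.
#' @param delta_qaly incremental QALYs.
#' @return a list with `delta_cost`, `delta_qaly`, `icer` (`NA` when
#'   dominance or indifference makes a ratio meaningless) and `status`: one
#'   of `"icer"`, `"dominant"` (cheaper and more effective), `"dominated"`,
#'   `"cost_saving_less_effective"` (ratio reported in the south-west
#'   quadrant is not a willingness-to-pay bound, so it is classified, not
#'   ratioed), `"cheaper_equal"`, `"costlier_equal"`, `"indifferent"`.
#' @export
#' @examples
#' icer(1000, 0.01)$icer  # 100000
icer <- function(delta_cost, delta_qaly) {
  status <-
    if (delta_qaly > 0 && delta_cost < 0) "dominant"
    else if (delta_qaly < 0 && delta_cost > 0) "dominated"
    else if (delta_qaly == 0 && delta_cost == 0) "indifferent"
    else if (delta_qaly == 0) {
      if (delta_cost < 0) "cheaper_equal" else "costlier_equal"
    }
    else if (delta_qaly < 0 && delta_cost < 0) "cost_saving_less_effective"
    else "icer"
  list(delta_cost = delta_cost, delta_qaly = delta_qaly,
       icer = if (status == "icer") delta_cost / delta_qaly else NA_real_,
       status = status)
}

#' Base-case cost-effectiveness analysis
#'
#' Evaluates each strategy on the same parameter set and forms pairwise
#' incrementals of the first (intervention) strategy against every other.
#'
#' @param params an `osteo_params` object.
#' @param strategies list of `osteo_strategy` objects; the first is the
#'   intervention.
#' @return an object of class `osteo_ce` with elements `results`
#'   (per-strategy tibble) and `incremental` (pairwise tibble).
#' @export
#' @examples
#' \donttest{
#' ce <- ce_analysis(default_parameters())
#' glance(ce)
#' }
ce_analysis <- function(params,
                        strategies = list(strategy_denosumab(),
                                          strategy_no_treatment(),
                                          strategy_alendronate())) {
  results <- purrr::map_dfr(strategies, evaluate_strategy, params = params)
  a <- results[1, ]
  incremental <- purrr::map_dfr(seq_len(nrow(results))[-1], function(i) {
    b <- results[i, ]
    ic <- icer(a$cost_total - b$cost_total, a$qaly - b$qaly)
    tibble::tibble(
      intervention = a$strategy, comparator = b$strategy,
      delta_cost = ic$delta_cost, delta_qaly = ic$delta_qaly,
      delta_ly = a$ly - b$ly, icer = ic$icer, status = ic$status
    )
  })
  structure(list(results = results, incremental = incremental),
            class = "osteo_ce")
}

#' @export
print.osteo_ce <- function(x, ...) {
  cat("<osteo_ce>\n")
  print(x$results[, c("strategy", "cost_total", "ev_any", "ly", "qaly")])
  print(x$incremental)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname ce_analysis
#' @param x an `osteo_ce` object.
#' @param ... unused.
#' @export
tidy.osteo_ce <- function(x, ...) {
  dplyr::left_join(
    x$results,
    dplyr::select(x$incremental, "comparator", "delta_cost", "delta_qaly",
                  "icer", "status"),
    by = c(strategy = "comparator")
  )
}

#' @rdname ce_analysis
#' @export
glance.osteo_ce <- function(x, ...) {
  inc <- x$incremental
  tibble::tibble(
    intervention = inc$intervention[1],
    n_comparators = nrow(inc),
    min_icer = suppressWarnings(min(inc$icer, na.rm = TRUE)),
    max_icer = suppressWarnings(max(inc$icer, na.rm = TRUE)),
    any_dominant = any(inc$status == "dominant")
  )
}

#' Scenario grid over alendronate treatment and holiday durations
#'
#' Re-runs the pairwise comparison of the (fixed) denosumab regimen against
#' alendronate variants with different first on-treatment and drug-holiday
#' durations inside the 10-year window (the second on-treatment block fills
#' the remainder), plus the 5-year-vs-5-year special case in which both
#' arms are capped at 5 years with no holiday.
#'
#' @param params an `osteo_params` object.
#' @param grid tibble with columns `on1`, `holiday`, `on2`, `den_years`;
#'   defaults to holiday durations 1-4 years after 5 years on treatment,
#'   on-treatment variations at a 2-year holiday, and the 5y-vs-5y case.
#' @return tibble: one row per combination with incremental results.
#' @export
scenario_grid <- function(params, grid = NULL) {
  if (is.null(grid)) {
    grid <- dplyr::distinct(dplyr::bind_rows(
      tibble::tibble(on1 = 5, holiday = 1:4, on2 = pmax(10 - 5 - 1:4, 0),
                     den_years = 10),
      tibble::tibble(on1 = 3:5, holiday = 2, on2 = 10 - 3:5 - 2,
                     den_years = 10),
      tibble::tibble(on1 = 5, holiday = 0, on2 = 0, den_years = 5)
    ))
  }
  purrr::pmap_dfr(grid, function(on1, holiday, on2, den_years) {
    den <- strategy_denosumab(on_years = den_years)
    alen <- strategy_alendronate(on1_years = on1, holiday_years = holiday,
                                 on2_years = on2)
    ce <- ce_analysis(params, list(den, alen))
    dplyr::bind_cols(
      tibble::tibble(on1 = on1, holiday = holiday, on2 = on2,
                     den_years = den_years),
      ce$incremental[, c("delta_cost", "delta_qaly", "icer", "status")]
    )
  })
}

#' One-way sensitivity analysis
#'
#' Each variant changes one input at a time relative to the base case -
#' either a parameter override (dotted path as in [apply_override()]), a
#' strategy modification (offset times, treatment durations), or full
#' persistence - and reports the incremental results of denosumab vs no
#' treatment and vs alendronate.
#'
#' @param params base-case `osteo_params`.
#' @param variants list of variant specs: each a list with `label` and any
#'   of `overrides` (named list of path = value), `den_offset`,
#'   `alen_offset`, `den_years`, `alen_regimen` (length-3 numeric),
#'   `full_persistence = TRUE`.
#' @return tibble with one row per variant (base case first) and columns
#'   for both comparisons.
#' @export
owsa <- function(params, variants) {
  run_one <- function(label, overrides = NULL, den_offset = NULL,
                      alen_offset = NULL, den_years = 10,
                      alen_regimen = c(5, 2, 3), full_persistence = FALSE) {
    p <- params
    for (path in names(overrides)) {
      p <- apply_override(p, path, overrides[[path]])
    }
    if (isTRUE(full_persistence)) {
      p$persistence$p <- rep(1, nrow(p$persistence))
      p <- validate_parameters(p)
    }
    den <- strategy_denosumab(on_years = den_years)
    if (!is.null(den_offset)) den$max_offset_years <- den_offset
    alen <- strategy_alendronate(alen_regimen[1], alen_regimen[2],
                                 alen_regimen[3])
    if (!is.null(alen_offset)) alen$max_offset_years <- alen_offset
    ce <- ce_analysis(p, list(den, strategy_no_treatment(), alen))
    inc <- ce$incremental
    vs_no <- inc[inc$comparator == "no_treatment", ]
    vs_al <- inc[grepl("^alendronate", inc$comparator), ]
    tibble::tibble(
      label = label,
      delta_cost_vs_no_tx = vs_no$delta_cost,
      delta_qaly_vs_no_tx = vs_no$delta_qaly,
      icer_vs_no_tx = vs_no$icer, status_vs_no_tx = vs_no$status,
      delta_cost_vs_alen = vs_al$delta_cost,
      delta_qaly_vs_alen = vs_al$delta_qaly,
      icer_vs_alen = vs_al$icer, status_vs_alen = vs_al$status
    )
  }
  base <- run_one("base_case")
  rows <- purrr::map_dfr(variants, function(v) do.call(run_one, v))
  dplyr::bind_rows(base, rows)
}

#' Standard one-way sensitivity variants
#'
#' The default variant list: start age, prevalent fracture fraction,
#' baseline T-score, modeling horizon, maximum treatment length, offset
#' times for both drugs, persistence extrapolation methods, full
#' persistence, discount rates, the excess-mortality attributable fraction
#' and the post-fracture mortality window.
#'
#' @return a list consumable by [owsa()].
#' @export
owsa_default_variants <- function() {
  ov <- function(...) list(...)
  list(
    list(label = "start_age_50", overrides = ov("config.start_age" = 50L)),
    list(label = "start_age_65", overrides = ov("config.start_age" = 65L)),
    list(label = "start_age_80", overrides = ov("config.start_age" = 80L)),
    list(label = "prevalent_vf_0", overrides = ov("config.prevalent_vf_fraction" = 0)),
    list(label = "prevalent_vf_100", overrides = ov("config.prevalent_vf_fraction" = 1)),
    list(label = "t_score_-2.8", overrides = ov("config.t_score" = -2.8)),
    list(label = "t_score_-3.0", overrides = ov("config.t_score" = -3.0)),
    list(label = "horizon_10y", overrides = ov("config.horizon" = "fixed",
                                               "config.horizon_years" = 10)),
    list(label = "horizon_15y", overrides = ov("config.horizon" = "fixed",
                                               "config.horizon_years" = 15)),
    list(label = "horizon_20y", overrides = ov("config.horizon" = "fixed",
                                               "config.horizon_years" = 20)),
    list(label = "treatment_5y", den_years = 5, alen_regimen = c(5, 0, 0)),
    list(label = "den_offset_0y", den_offset = 0),
    list(label = "den_offset_2y", den_offset = 2),
    list(label = "alen_offset_1y", alen_offset = 1),
    list(label = "alen_offset_3y", alen_offset = 3),
    list(label = "alen_offset_5y", alen_offset = 5),
    list(label = "persistence_last_interval_rate",
         overrides = ov("config.persistence_extrapolation" = "last_interval_rate")),
    list(label = "persistence_overall_rate",
         overrides = ov("config.persistence_extrapolation" = "overall_rate")),
    list(label = "persistence_100pct", full_persistence = TRUE),
    list(label = "discount_0pct", overrides = ov("config.discount_rate_annual" = 0)),
    list(label = "discount_5pct", overrides = ov("config.discount_rate_annual" = 0.05)),
    list(label = "excess_mortality_0", overrides = ov("config.excess_mortality_attribution" = 0)),
    list(label = "excess_mortality_18", overrides = ov("config.excess_mortality_attribution" = 0.18)),
    list(label = "excess_mortality_42", overrides = ov("config.excess_mortality_attribution" = 0.42)),
    list(label = "excess_mortality_100", overrides = ov("config.excess_mortality_attribution" = 1)),
    list(label = "mortality_window_3y", overrides = ov("config.excess_mortality_years" = 3)),
    list(label = "mortality_window_5y", overrides = ov("config.excess_mortality_years" = 5)),
    list(label = "mortality_window_10y", overrides = ov("config.excess_mortality_years" = 10)),
    list(label = "mortality_window_lifetime", overrides = ov("config.excess_mortality_years" = 60))
  )
}
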