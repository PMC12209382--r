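# Parameter container: single source of truth for every model input.
#
# Printed inputs (relative risks, efficacy, persistence, costs, utilities)
# carry their published values as package defaults; inputs the primary
# sources never print (female life table, general-population fracture
# incidence, population mean T-scores, nursing-home admission/stay after hip
# fracture) come from the synthetic generators in synthetic-data.R and are
# flagged as assumptions wherever they are serialized.

#' Default model parameters
#'
#' Builds the fully populated, validated parameter set used by the base-case
#' analysis: a cohort of postmenopausal women entering at age 72 with a
#' T-score of -2.5 and a 23.6% prevalence of vertebral fracture, 6-month
#' cycles, a lifetime horizon and 3% annual discounting.
#'
#' Tables that are assumptions rather than published values are generated by
#' [gen_life_table()], [gen_incidence_table()] and [gen_population_tscore()]
#' with `synthetic_seed`; they are deterministic given the seed.
#'
#' @param synthetic_seed integer seed forwarded to the synthetic-input
#'   generators.
#' @return An object of class `osteo_params`: a named list with components
#'   `config`, `rr`, `efficacy`, `persistence`, `costs`, `utilities`,
#'   `mortality` and `incidence`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$rr$per_sd[["hip"]]
default_parameters <- function(synthetic_seed = 1L) {
  config <- list(
    start_age = 72L,
    cycle_length = 0.5,
    horizon = "lifetime",
    horizon_years = NA_real_,
    max_age = 100L,
    discount_rate_annual = 0.03,
    discount_timing = "end",
    t_score = -2.5,
    prevalent_vf_fraction = 0.236,
    excess_mortality_attribution = 0.30,
    excess_mortality_years = 8,
    fracture_effect_cycles = 2L,
    age_lookup = "step",
    hip_gradient = "marshall",
    disease_rr_rule = "max",
    persistence_extrapolation = "last_value",
    persistence_reset_after_holiday = FALSE
  )

  rr <- list(
    per_sd = c(hip = 2.60, vertebral = 1.80, wrist = 1.40, other = 1.60),
    hip_per_sd_by_age = tibble::tibble(age = c(65, 70), rr = c(2.89, 2.78)),
    prior_fx = tibble::tibble(
      site = c("hip", "hip", "vertebral", "wrist", "other"),
      age = c(65, 70, NA, NA, NA),
      rr = c(2.28, 1.90, 4.40, 1.40, 1.90)
    ),
    bmd_adjustment_factor = 0.90,
    mean_pop_tscore = gen_population_tscore(synthetic_seed)
  )

  efficacy <- tibble::tibble(
    drug = rep(c("alendronate", "denosumab"), each = 12L),
    site = rep(rep(c("hip", "vertebral", "wrist", "other"), times = 3L), 2L),
    months = rep(rep(c(12, 24, 36), each = 4L), 2L),
    rr = c(
      # alendronate vs placebo
      0.86, 0.51, 0.77, 0.77,
      0.51, 0.37, 0.53, 0.53,
      0.52, 0.51, 0.62, 0.62,
      # denosumab vs placebo
      0.55, 0.39, 0.84, 0.84,
      0.47, 0.29, 0.79, 0.79,
      0.28, 0.33, 0.82, 0.82
    )
  )

  persistence <- tibble::tibble(
    drug = rep(c("alendronate", "denosumab"), each = 7L),
    month = rep(seq(0, 36, by = 6), 2L),
    p = c(
      1.000, 0.561, 0.388, 0.298, 0.247, 0.203, 0.172,
      1.000, 0.936, 0.727, 0.596, 0.503, 0.432, 0.380
    )
  )

  costs <- list(
    fracture = tibble::tibble(
      site = c(rep("hip", 4L), rep("vertebral", 4L), "wrist", "wrist",
               "other", "other"),
      year = c("1", "1", "2plus", "2plus", "1", "1", "2plus", "2plus",
               "1", "1", "1", "1"),
      age_band = rep(c("50_64", "65plus"), 6L),
      cost = c(67115, 51760, 11145, 7896,
               33923, 23949, 8455, 5943,
               16279, 21731, 16279, 21731)
    ),
    unit = c(dxa = 38.95, physician_visit = 90.87,
             iv_injection = 62.58, nurse_visit = 14.31),
    ltc_per_day = 216,
    # Never printed in the primary sources: documented assumptions.
    ltc_admission_prob_after_hip = 0.20,
    ltc_mean_stay_days = 180
  )

  utilities <- list(
    baseline = tibble::tibble(
      age = c(50, 60, 70, 80),
      utility = c(0.837, 0.811, 0.771, 0.724)
    ),
    multiplier = tibble::tibble(
      site = c("hip", "hip", "vertebral", "vertebral", "wrist", "other"),
      year = c("1", "2plus", "1", "2plus", "1", "1"),
      mult = c(0.550, 0.860, 0.680, 0.850, 0.830, 0.830)
    )
  )

  mortality <- list(
    life_table = gen_life_table(synthetic_seed),
    rr_post_fx = gen_post_fracture_mortality_rr(synthetic_seed)
  )

  params <- structure(
    list(
      config = config, rr = rr, efficacy = efficacy,
      persistence = persistence, costs = costs, utilities = utilities,
      mortality = mortality, incidence = gen_incidence_table(synthetic_seed)
    ),
    class = "osteo_params"
  )
  validate_parameters(params)
}

#' Validate a parameter set
#'
#' Checks every documented invariant (proportions in \[0,1\], positive
#' relative risks, nonincreasing persistence starting at 1, year-2+ fracture
#' costs not exceeding year-1 costs, utilities and multipliers in (0,1\],
#' death probabilities in \[0,1\], nonnegative incidence) and returns the set
#' invisibly if everything holds.
#'
#' @param params an `osteo_params` object.
#' @return `params`, invisibly; otherwise an error naming the offending
#'   field and value.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, value, why) {
    stop(sprintf("invalid parameter `%s` = %s: %s", field,
                 paste(format(value), collapse = ", "), why), call. = FALSE)
  }
  cfg <- params$config
  required <- c("config", "rr", "efficacy", "persistence", "costs",
                "utilities", "mortality", "incidence")
  missing <- setdiff(required, names(params))
  if (length(missing) > 0L) {
    stop("parameter bundle is missing required table(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (cfg$start_age < 50) fail("config.start_age", cfg$start_age, "must be >= 50")
  if (!identical(as.numeric(cfg$cycle_length), 0.5)) {
    fail("config.cycle_length", cfg$cycle_length, "model is defined on 6-month cycles")
  }
  if (cfg$discount_rate_annual < 0) {
    fail("config.discount_rate_annual", cfg$discount_rate_annual, "must be >= 0")
  }
  for (f in c("prevalent_vf_fraction", "excess_mortality_attribution")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      fail(paste0("config.", f), cfg[[f]], "must be a proportion in [0, 1]")
    }
  }
  if (cfg$excess_mortality_years <= 0) {
    fail("config.excess_mortality_years", cfg$excess_mortality_years, "must be > 0")
  }
  if (any(params$rr$per_sd <= 0)) {
    fail("rr.per_sd", params$rr$per_sd, "relative risks must be > 0")
  }
  if (any(params$rr$prior_fx$rr <= 0)) {
    fail("rr.prior_fx.rr", params$rr$prior_fx$rr, "relative risks must be > 0")
  }
  if (any(params$efficacy$rr <= 0 | params$efficacy$rr > 1.5)) {
    fail("efficacy.rr", params$efficacy$rr, "treatment RRs must lie in (0, 1.5]")
  }
  per_drug <- split(params$persistence, params$persistence$drug)
  for (d in names(per_drug)) {
    tab <- per_drug[[d]][order(per_drug[[d]]$month), ]
    if (abs(tab$p[tab$month == 0] - 1) > 1e-12) {
      fail(paste0("persistence.", d, ".0"), tab$p[tab$month == 0],
           "persistence at month 0 must be 1.0")
    }
    if (any(tab$p < 0 | tab$p > 1)) {
      fail(paste0("persistence.", d), tab$p, "must lie in [0, 1]")
    }
    if (any(diff(tab$p) > 1e-12)) {
      fail(paste0("persistence.", d), tab$p, "must be nonincreasing in month")
    }
  }
  fc <- params$costs$fracture
  if (any(fc$cost < 0)) fail("costs.fracture.cost", fc$cost, "costs must be >= 0")
  for (s in unique(fc$site)) {
    for (b in unique(fc$age_band)) {
      y1 <- fc$cost[fc$site == s & fc$age_band == b & fc$year == "1"]
      y2 <- fc$cost[fc$site == s & fc$age_band == b & fc$year == "2plus"]
      if (length(y1) == 1L && length(y2) == 1L && y2 > y1) {
        fail(sprintf("costs.fracture.%s.2plus.%s", s, b), y2,
             "year-2+ cost must not exceed year-1 cost")
      }
    }
  }
  if (any(params$costs$unit < 0)) {
    fail("costs.unit", params$costs$unit, "unit costs must be >= 0")
  }
  p_ltc <- params$costs$ltc_admission_prob_after_hip
  if (p_ltc < 0 || p_ltc > 1) {
    fail("costs.ltc_admission_prob_after_hip", p_ltc, "must be a proportion")
  }
  ub <- params$utilities$baseline$utility
  if (any(ub <= 0 | ub > 1)) {
    fail("utilities.baseline.utility", ub, "utilities must lie in (0, 1]")
  }
  um <- params$utilities$multiplier$mult
  if (any(um <= 0 | um > 1)) {
    fail("utilities.multiplier.mult", um, "multipliers must lie in (0, 1]")
  }
  lt <- params$mortality$life_table
  if (any(lt$q < 0 | lt$q > 1)) {
    fail("mortality.life_table.q", range(lt$q), "death probabilities must lie in [0, 1]")
  }
  if (any(params$mortality$rr_post_fx$rr < 1)) {
    fail("mortality.rr_post_fx.rr", params$mortality$rr_post_fx$rr,
         "post-fracture mortality RRs must be >= 1")
  }
  if (any(params$incidence$rate < 0)) {
    fail("incidence.rate", range(params$incidence$rate), "rates must be >= 0")
  }
  invisible(params)
}

#' @export
print.osteo_params <- function(x, ...) {
  cfg <- x$config
  cat("<osteo_params>\n")
  cat(sprintf("  cohort: start age %d, T-score %.1f, prevalent VF %.1f%%\n",
              cfg$start_age, cfg$t_score, 100 * cfg$prevalent_vf_fraction))
  cat(sprintf("  horizon: %s (max age %d), discount %.1f%%/yr\n",
              cfg$horizon, cfg$max_age, 100 * cfg$discount_rate_annual))
  cat(sprintf("  drugs with efficacy/persistence data: %s\n",
              paste(unique(x$efficacy$drug), collapse = ", ")))
  invisible(x)
}

# ---- dotted-path overrides -------------------------------------------------

.path_candidates <- function(node) {
  if (is.data.frame(node)) {
    keys <- utils::head(names(node), -1L)
    vals <- lapply(keys, function(k) unique(node[[k]]))
    return(apply(expand.grid(vals, stringsAsFactors = FALSE), 1L,
                 paste, collapse = "."))
  }
  names(node)
}

.suggest <- function(target, candidates) {
  if (length(candidates) == 0L) return(character())
  d <- utils::adist(target, candidates, ignore.case = TRUE)
  candidates[order(d)][seq_len(min(3L, length(candidates)))]
}

#' Override a single parameter by dotted path
#'
#' Returns a new parameter set differing from `params` only at `path`; the
#' original is untouched. Scalars are addressed through list names
#' (`"config.discount_rate_annual"`, `"rr.per_sd.hip"`); table cells through
#' the table's key columns in order
#' (`"efficacy.denosumab.hip.12"`, `"persistence.alendronate.6"`,
#' `"costs.fracture.hip.1.65plus"`, `"utilities.baseline.70"`).
#'
#' This is the primitive behind the one-way sensitivity analysis: every
#' alternative-value row is a pure override of the base-case set.
#'
#' @param params an `osteo_params` object.
#' @param path dotted field name.
#' @param value replacement value (scalar).
#' @param validate revalidate the resulting set (default `TRUE`).
#' @return a new `osteo_params` object.
#' @export
#' @examples
#' p <- default_parameters()
#' p2 <- apply_override(p, "config.discount_rate_annual", 0.05)
#' p2$config$discount_rate_annual
apply_override <- function(params, path, value, validate = TRUE) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2L) {
    stop("override path must have at least two components, got `", path, "`",
         call. = FALSE)
  }
  assign_in <- function(node, parts, trail) {
    key <- parts[[1]]
    if (is.data.frame(node)) {
      keys <- utils::head(names(node), -1L)
      valcol <- utils::tail(names(node), 1L)
      if (length(parts) != length(keys)) {
        stop(sprintf(
          "path `%s` does not address a cell of table `%s` (keys: %s)",
          path, paste(trail, collapse = "."), paste(keys, collapse = ", ")),
          call. = FALSE)
      }
      sel <- rep(TRUE, nrow(node))
      for (i in seq_along(keys)) {
        col <- node[[keys[i]]]
        want <- parts[[i]]
        sel <- sel & (!is.na(col) & as.character(col) == want |
                        (is.na(col) & want == "NA"))
      }
      if (sum(sel) != 1L) {
        stop(sprintf(
          "path `%s` matches %d rows of table `%s`; nearest valid cells: %s",
          path, sum(sel), paste(trail, collapse = "."),
          paste(.suggest(paste(parts, collapse = "."),
                         .path_candidates(node)), collapse = ", ")),
          call. = FALSE)
      }
      node[[valcol]][sel] <- value
      return(node)
    }
    if (!key %in% names(node)) {
      stop(sprintf(
        "unknown parameter path `%s` at `%s`; nearest valid paths: %s",
        path, paste(c(trail, key), collapse = "."),
        paste(paste(c(trail, .suggest(key, names(node))), collapse = "."),
              collapse = ", ")),
        call. = FALSE)
    }
    if (length(parts) == 1L) {
      if (is.list(node[[key]]) && !is.data.frame(node[[key]])) {
        stop(sprintf("path `%s` names a table, not a scalar", path),
             call. = FALSE)
      }
      if (length(node[[key]]) > 1L && !is.null(names(node[[key]]))) {
        stop(sprintf("path `%s` names a vector; add a component to pick one of: %s",
                     path, paste(names(node[[key]]), collapse = ", ")),
             call. = FALSE)
      }
      node[[key]] <- value
      return(node)
    }
    rest <- parts[-1L]
    child <- node[[key]]
    if (is.numeric(child) && !is.null(names(child)) && length(rest) == 1L) {
      if (!rest %in% names(child)) {
        stop(sprintf("unknown element `%s` of `%s`; valid: %s", rest,
                     paste(c(trail, key), collapse = "."),
                     paste(names(child), collapse = ", ")), call. = FALSE)
      }
      child[[rest]] <- value
      node[[key]] <- child
      return(node)
    }
    node[[key]] <- assign_in(child, rest, c(trail, key))
    node
  }
  out <- assign_in(unclass(params), parts, character())
  out <- structure(out, class = "osteo_params")
  if (validate) validate_parameters(out)
  out
}

# ---- age-keyed lookup ------------------------------------------------------

# Step lookup at the largest key <= age (default), or linear interpolation
# when the config selects it. Ages below the smallest key are an error for
# step lookup: the tables are defined from age 50.
age_lookup <- function(ages, values, age, method = "step") {
  if (age < min(ages)) {
    stop(sprintf("age %.1f below table support (min %s)", age, min(ages)),
         call. = FALSE)
  }
  ord <- order(ages)
  ages <- ages[ord]
  values <- values[ord]
  if (method == "linear") {
    return(stats::approx(ages, values, xout = age, rule = 2)$y)
  }
  values[findInterval(age, ages)]
}

# ---- bundle serialization --------------------------------------------------

.BUNDLE_TABLES <- c("rr.hip_per_sd_by_age", "rr.prior_fx", "rr.mean_pop_tscore",
                    "efficacy", "persistence", "costs.fracture",
                    "utilities.baseline", "utilities.multiplier",
                    "mortality.life_table", "mortality.rr_post_fx", "incidence")
.SYNTHETIC_TABLES <- c("rr.mean_pop_tscore", "mortality.life_table",
                       "mortality.rr_post_fx", "incidence")

.get_path <- function(params, dotted) {
  node <- params
  for (k in strsplit(dotted, ".", fixed = TRUE)[[1]]) node <- node[[k]]
  node
}

.set_path <- function(params, dotted, value) {
  parts <- strsplit(dotted, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    params[[parts]] <- value
  } else {
    params[[parts[1]]] <- .set_path(params[[parts[1]]], paste(parts[-1L],
                                                              collapse = "."),
                                    value)
  }
  params
}

#' Write a parameter bundle to disk
#'
#' Serializes a parameter set as a YAML manifest (`manifest.yaml`: the scalar
#' configuration, unit costs, and the file name of each table) plus one CSV
#' per table. Synthetic tables carry an `ASSUMED` banner comment in their
#' first line. [load_parameters()] reads the result back losslessly.
#'
#' @param params an `osteo_params` object.
#' @param dir directory to create/populate.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    bundle_format = 1L,
    config = params$config,
    rr = list(per_sd = as.list(params$rr$per_sd),
              bmd_adjustment_factor = params$rr$bmd_adjustment_factor),
    costs = list(unit = as.list(params$costs$unit),
                 ltc_per_day = params$costs$ltc_per_day,
                 ltc_admission_prob_after_hip =
                   params$costs$ltc_admission_prob_after_hip,
                 ltc_mean_stay_days = params$costs$ltc_mean_stay_days),
    tables = stats::setNames(
      as.list(paste0(gsub(".", "_", .BUNDLE_TABLES, fixed = TRUE), ".csv")),
      .BUNDLE_TABLES
    )
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (tb in .BUNDLE_TABLES) {
    f <- file.path(dir, manifest$tables[[tb]])
    con <- file(f, open = "wt")
    if (tb %in% .SYNTHETIC_TABLES) {
      writeLines("# ASSUMED - synthetic stand-in generated by osteomark, not a published table", con)
    }
    utils::write.csv(.get_path(params, tb), con, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Load (and layer) a parameter bundle
#'
#' With `path = NULL` returns the bundled defaults. Given a bundle directory
#' written by [write_bundle()] (or following the same schema), reads the
#' manifest and every referenced table, fills anything the file omits from
#' the defaults, validates, and returns the result. A manifest that names a
#' missing table file is a schema error naming that table.
#'
#' @param path bundle directory containing `manifest.yaml`, or `NULL` for
#'   defaults.
#' @param synthetic_seed seed for the default synthetic tables used to fill
#'   omissions.
#' @return an `osteo_params` object.
#' @export
load_parameters <- function(path = NULL, synthetic_seed = 1L) {
  params <- default_parameters(synthetic_seed)
  if (is.null(path)) return(params)
  mf <- file.path(path, "manifest.yaml")
  if (!file.exists(mf)) {
    stop("no manifest.yaml in bundle directory `", path, "`", call. = FALSE)
  }
  manifest <- yaml::read_yaml(mf)
  raw <- unclass(params)
  for (grp in c("config")) {
    for (k in names(manifest[[grp]])) raw[[grp]][[k]] <- manifest[[grp]][[k]]
  }
  if (!is.null(manifest$rr$per_sd)) {
    raw$rr$per_sd <- unlist(manifest$rr$per_sd)[names(raw$rr$per_sd)]
  }
  if (!is.null(manifest$rr$bmd_adjustment_factor)) {
    raw$rr$bmd_adjustment_factor <- manifest$rr$bmd_adjustment_factor
  }
  if (!is.null(manifest$costs)) {
    if (!is.null(manifest$costs$unit)) {
      raw$costs$unit <- unlist(manifest$costs$unit)[names(raw$costs$unit)]
    }
    for (k in c("ltc_per_day", "ltc_admission_prob_after_hip",
                "ltc_mean_stay_days")) {
      if (!is.null(manifest$costs[[k]])) raw$costs[[k]] <- manifest$costs[[k]]
    }
  }
  for (tb in names(manifest$tables)) {
    if (!tb %in% .BUNDLE_TABLES) {
      stop("manifest references unknown table `", tb, "`", call. = FALSE)
    }
    f <- file.path(path, manifest$tables[[tb]])
    if (!file.exists(f)) {
      stop("bundle is missing required table `", tb, "` (file ",
           manifest$tables[[tb]], ")", call. = FALSE)
    }
    tab <- readr::read_csv(f, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    template <- .get_path(raw, tb)
    miss <- setdiff(names(template), names(tab))
    if (length(miss) > 0L) {
      stop("table `", tb, "` is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    raw <- .set_path(raw, tb, tibble::as_tibble(tab[names(template)]))
  }
  validate_parameters(structure(raw, class = "osteo_params"))
}
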