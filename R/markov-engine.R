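# Cohort engine: advances occupancy over (health state x time-in-state x
# prior-fracture/prior-VF flags x treatment stratum) in 6-month cycles.
#
# Conventions (mirrored exactly by the microsimulation oracle):
#   * transitions happen at the start of each cycle, death before fracture;
#     the post-transition state is occupied for the cycle and accrues
#     life-years, QALYs and state costs, discounted at cycle end;
#   * within a cycle competing fractures resolve by severity hierarchy
#     (hip > vertebral > wrist > other); from hip/vertebral acute and post
#     states, lower-hierarchy fractures do not change state but are recorded
#     as downstream events (occupancy x marginal site probability) feeding
#     cost and disutility accrual only;
#   * the 8-year excess-mortality window is carried by 16 half-year tunnel
#     compartments for post-hip/post-vert, by the acute+convalescent cycles
#     plus a well-state clock for "other" fractures, and not at all for
#     wrist fractures (no published excess);
#   * persistence is handled as strata: one "on" stratum, one merged "off"
#     stratum, and short-lived discontinuation strata each carrying the
#     months-on-treatment clock that fixes residual efficacy and the
#     dynamic offset;
#   * an incident vertebral fracture sets a lifetime flag; flagged occupancy
#     in hip/post-hip states carries the vertebral excess-mortality
#     component (while within the hip 8-year window) and the chronic
#     vertebral utility multiplier.

# ---- shared per-cycle inputs ----------------------------------------------

# Everything that depends only on (strategy, params, cycle): computed once
# and shared by the cohort engine and the microsimulation oracle so the two
# cannot drift apart.
model_frame <- function(strat, params) {
  cfg <- params$config
  n_cycles <- if (identical(cfg$horizon, "lifetime")) {
    as.integer(2 * (cfg$max_age - cfg$start_age))
  } else {
    as.integer(2 * cfg$horizon_years)
  }
  sched <- strategy_schedule(strat, max(n_cycles, 1L))
  if (n_cycles == 0L) sched <- sched[0, ]
  pers <- if (!is.na(strat$drug) && n_cycles > 0L) {
    discontinuation_flow(persistence_curve(params, strat$drug), strat, sched)
  } else if (n_cycles > 0L) {
    tibble::tibble(cycle = sched$cycle, kind = sched$kind,
                   persistent = 0, flow = 0,
                   months_on_at_disc = 0, off_ref = sched$calendar_start)
  } else NULL

  t_idx <- seq_len(n_cycles)
  ages <- cfg$start_age + 0.5 * (t_idx - 1)
  iage <- floor(ages + 1e-9)
  # vectorized step/linear age lookup (same rule as age_lookup())
  vlook <- function(tab_age, tab_val, a) {
    ord <- order(tab_age)
    ta <- tab_age[ord]; tv <- tab_val[ord]
    if (length(a) > 0L && min(a) < ta[1L]) {
      stop(sprintf("age %.1f below table support (min %s)", min(a), ta[1L]),
           call. = FALSE)
    }
    if (identical(cfg$age_lookup, "linear")) {
      stats::approx(ta, tv, xout = a, rule = 2)$y
    } else {
      tv[findInterval(a, ta)]
    }
  }
  lt <- params$mortality$life_table
  q_annual <- vlook(lt$age, lt$q, iage)
  q_cycle <- 1 - (1 - q_annual)^0.5

  mk <- function(cols, f) {
    out <- matrix(0, nrow = n_cycles, ncol = length(cols),
                  dimnames = list(NULL, cols))
    for (s in cols) out[, s] <- f(s)
    out
  }
  rrx <- mk(c("hip", "vertebral", "other"), function(s) {
    tab <- params$mortality$rr_post_fx[params$mortality$rr_post_fx$site == s, ]
    vlook(tab$age, tab$rr, iage)
  })
  g <- mk(.SITES, function(s) {
    tab <- params$incidence[params$incidence$site == s, ]
    vlook(tab$age, tab$rate, iage)
  })
  ts_tab <- params$rr$mean_pop_tscore
  mean_t <- vlook(ts_tab$age, ts_tab$t_score, iage)
  dis0 <- mk(.SITES, function(s) {
    grad <- if (s == "hip" && identical(cfg$hip_gradient, "age_specific")) {
      vlook(params$rr$hip_per_sd_by_age$age, params$rr$hip_per_sd_by_age$rr,
            iage)
    } else params$rr$per_sd[[s]]
    grad^(mean_t - cfg$t_score)
  })
  dis1 <- mk(.SITES, function(s) {
    tab <- params$rr$prior_fx[params$rr$prior_fx$site == s, ]
    pf <- if (nrow(tab) == 1L && is.na(tab$age)) {
      rep(tab$rr, n_cycles)
    } else vlook(tab$age, tab$rr, iage)
    pf <- pf * params$rr$bmd_adjustment_factor
    switch(cfg$disease_rr_rule,
           max = pmax(dis0[, s], pf),
           multiply = dis0[, s] * pf,
           stop("unknown disease_rr_rule", call. = FALSE))
  })

  eff_on <- mk(.SITES, function(s) {
    treatment_rr(params, strat$drug, s, sched$months_on_end)
  })

  ub <- params$utilities$baseline
  u_base <- vlook(ub$age, ub$utility, iage)
  fc <- params$costs$fracture
  fcost <- function(s, year) {
    pick <- function(band) {
      hit <- fc$cost[fc$site == s & fc$year == year & fc$age_band == band]
      if (length(hit) != 1L) 0 else hit
    }
    ifelse(iage >= 65, pick("65plus"), pick("50_64"))
  }
  costs <- lapply(c(hip = "hip", vertebral = "vertebral", wrist = "wrist",
                    other = "other"), function(s) {
    list(y1 = fcost(s, "1"),
         y2 = if (s %in% c("hip", "vertebral")) fcost(s, "2plus") else
           rep(0, n_cycles))
  })

  exp_t <- switch(cfg$discount_timing,
                  end = t_idx, start = t_idx - 1, mid = t_idx - 0.5)
  df <- discount_factor(cfg$discount_rate_annual, exp_t)

  mult <- list(
    h1 = utility_multiplier(params, "hip", "1"),
    h2 = utility_multiplier(params, "hip", "2plus"),
    v1 = utility_multiplier(params, "vertebral", "1"),
    v2 = utility_multiplier(params, "vertebral", "2plus"),
    w1 = utility_multiplier(params, "wrist", "1"),
    o1 = utility_multiplier(params, "other", "1")
  )

  list(
    n_cycles = n_cycles, ages = ages, iage = iage, sched = sched, pers = pers,
    q_cycle = q_cycle, rrx = rrx, g = g, dis0 = dis0, dis1 = dis1,
    eff_on = eff_on, u_base = u_base, costs = costs, df = df, mult = mult,
    att = cfg$excess_mortality_attribution,
    mort_window = as.integer(round(2 * cfg$excess_mortality_years)),
    drug_cost_cycle = ifelse(sched$kind == "on",
                             cycle_drug_and_monitoring_cost(strat, params, 1), 0),
    drug_only_cycle = ifelse(sched$kind == "on",
                             0.5 * strat$annual_drug_cost, 0),
    ltc_per_event = ltc_cost_accrual(1, params),
    max_offset_months = 12 * strat$max_offset_years
  )
}

# Excess-mortality relative risk per compartment. Returns RRe such that
# q_state = q_cycle * (1 + att * (RRe - 1)). `win` is the mortality window
# in cycles (default 16 = 8 years).
.excess_rr <- function(st, ck, vf, rr_hip, rr_vert, rr_other, win = 16L) {
  hipw <- (st == 2L) | (st == 6L & ck <= (win - 1L))
  vertw <- (st == 3L) | (st == 7L & ck <= (win - 1L))
  othw <- (st == 5L) | (st == 1L & ck >= 2L & ck <= (win - 1L))
  1 +
    ifelse(hipw, rr_hip - 1, 0) +
    ifelse(vertw, rr_vert - 1, 0) +
    ifelse(othw, rr_other - 1, 0) +
    ifelse(hipw & vf == 2L, rr_vert - 1, 0)
}

# Utility multiplier per compartment.
.state_mult <- function(st, ck, vf, mult) {
  m <- rep(1, length(st))
  m[st == 2L] <- mult$h1
  m[st == 6L & ck == 1L] <- mult$h1
  m[st == 6L & ck >= 2L] <- mult$h2
  m[st == 3L] <- mult$v1
  m[st == 7L & ck == 1L] <- mult$v1
  m[st == 7L & ck >= 2L] <- mult$v2
  m[st == 4L] <- mult$w1
  m[st == 5L] <- mult$o1
  # lifetime vertebral consequence for incident-VF patients in hip states
  hip_vf <- vf == 2L & (st == 2L | st == 6L)
  m[hip_vf] <- m[hip_vf] * mult$v2
  m
}

# Per-cycle state cost (half-yearly) per compartment.
.state_cost <- function(st, ck, cy) {
  cost <- numeric(length(st))
  cost[st == 2L] <- cy$hip$y1 / 2
  cost[st == 6L & ck == 1L] <- cy$hip$y1 / 2
  cost[st == 6L & ck >= 2L] <- cy$hip$y2 / 2
  cost[st == 3L] <- cy$vertebral$y1 / 2
  cost[st == 7L & ck == 1L] <- cy$vertebral$y1 / 2
  cost[st == 7L & ck >= 2L] <- cy$vertebral$y2 / 2
  cost[st == 4L] <- cy$wrist$y1 / 2
  cost[st == 5L] <- cy$other$y1 / 2
  cost
}

# Category of state cost by site (for the per-category ledger).
.state_site <- function(st) {
  c(NA, "hip", "vertebral", "wrist", "other", "hip", "vertebral")[st]
}

#' Per-cycle death probability
#'
#' Baseline per-cycle mortality is `1 - (1 - q_annual)^0.5`. While within
#' the 8-year post-fracture window of a hip, vertebral or other fracture
#' the excess is scaled by the attributable fraction:
#' `q = q_cycle * (1 + attribution * (RR - 1))`, where `RR` may carry an
#' additional vertebral component (`weighted_vf_rr`) for prior-VF-weighted
#' hip states. Probabilities are clipped at 1 with a warning.
#'
#' @param age age in years.
#' @param state health state name.
#' @param cycles_since_fx cycles since the fracture event (0 = acute cycle).
#' @param params an `osteo_params` object.
#' @param weighted_vf_rr additional blended vertebral RR for hip states
#'   (default 1 = no blending).
#' @return probability of death during the cycle.
#' @export
#' @examples
#' death_prob(72, "well", params = default_parameters())
death_prob <- function(age, state, cycles_since_fx = 0L, params,
                       weighted_vf_rr = 1) {
  lt <- params$mortality$life_table
  q_annual <- age_lookup(lt$age, lt$q, age, params$config$age_lookup)
  q_cycle <- 1 - (1 - q_annual)^0.5
  win <- as.integer(round(2 * params$config$excess_mortality_years))
  site <- switch(state, hip_fx = , post_hip = "hip",
                 vert_fx = , post_vert = "vertebral",
                 other_fx = "other", NULL)
  rr <- 1
  if (!is.null(site) && cycles_since_fx < win) {
    tab <- params$mortality$rr_post_fx[params$mortality$rr_post_fx$site == site, ]
    rr <- age_lookup(tab$age, tab$rr, age, params$config$age_lookup)
  }
  rr <- rr + (weighted_vf_rr - 1)
  q <- q_cycle * (1 + params$config$excess_mortality_attribution * (rr - 1))
  if (q > 1) {
    warning("death probability clipped at 1", call. = FALSE)
    q <- 1
  }
  q
}

#' Prior-vertebral-fracture weight
#'
#' The incremental proportion of patients with vertebral fracture divided by
#' the proportion without a prior vertebral fracture at the beginning of the
#' period considered; used to weight the extra vertebral mortality and
#' utility consequences onto the hip and post-hip states.
#'
#' @param incremental_vf_prop proportion with an in-model (incident)
#'   vertebral fracture.
#' @param baseline_no_vf_prop proportion without prior vertebral fracture at
#'   baseline (> 0).
#' @export
#' @examples
#' prior_vf_weight(0.1, 1 - 0.236)
prior_vf_weight <- function(incremental_vf_prop, baseline_no_vf_prop) {
  if (any(baseline_no_vf_prop <= 0)) {
    stop("baseline_no_vf_prop must be > 0", call. = FALSE)
  }
  incremental_vf_prop / baseline_no_vf_prop
}

# ---- the cycle loop --------------------------------------------------------

#' Run the cohort trace
#'
#' Initializes the cohort at the starting age (with the configured prevalent
#' vertebral fracture fraction flagged) and advances it cycle by cycle to
#' the horizon, recording occupancy, deaths, fracture events (routed and
#' downstream), and discounted/undiscounted costs by category, life-years
#' and QALYs.
#'
#' @param strat an `osteo_strategy`.
#' @param params an `osteo_params` object.
#' @param store_compartments keep the full per-cycle compartment table
#'   (memory-heavier; needed by [export_trace()]).
#' @return an object of class `osteo_trace`; its `cycles` element is a
#'   tibble with one row per cycle.
#' @export
#' @examples
#' tr <- run_trace(strategy_no_treatment(), default_parameters())
#' sum(tr$cycles$ev_hip)
run_trace <- function(strat, params, store_compartments = FALSE) {
  fr <- model_frame(strat, params)
  cfg <- params$config
  pvf <- cfg$prevalent_vf_fraction

  has_tx <- !is.na(strat$drug) && fr$n_cycles > 0L &&
    any(fr$sched$kind != "off")
  # strata table, grown as needed; id indexes rows
  strata <- data.frame(
    status = if (has_tx) "on" else "never",
    m_on = 0, off_ref = 0, stringsAsFactors = FALSE
  )

  # compartments: state, clock, fx flag, vf flag (0 none / 1 prevalent /
  # 2 incident), stratum id, mass
  st <- c(1L, 1L); ck <- c(0L, 0L)
  fx <- c(0L, 1L); vf <- c(0L, 1L)
  sid <- c(1L, 1L)
  m <- c(1 - pvf, pvf)
  keep <- m > 0
  st <- st[keep]; ck <- ck[keep]; fx <- fx[keep]; vf <- vf[keep]
  sid <- sid[keep]; m <- m[keep]

  n_cyc <- fr$n_cycles
  rec <- matrix(0, nrow = n_cyc, ncol = 26)
  colnames(rec) <- c("alive", "deaths", "ev_hip", "ev_vert", "ev_wrist",
                     "ev_other", "ds_vert", "ds_wrist", "ds_other",
                     "cost_drug", "cost_mgmt", "cost_hip", "cost_vert",
                     "cost_wrist", "cost_other", "cost_ltc",
                     "qaly", "ly",
                     "cost_drug_u", "cost_mgmt_u", "cost_hip_u",
                     "cost_vert_u", "cost_wrist_u", "cost_other_u",
                     "cost_ltc_u", "qaly_u")
  comp_log <- if (store_compartments) vector("list", n_cyc) else NULL
  cum_dead <- 0
  P_prev <- 1
  win <- fr$mort_window

  for (t in seq_len(n_cyc)) {
    kind_t <- fr$sched$kind[t]
    kind_prev <- if (t == 1L) kind_t else fr$sched$kind[t - 1L]

    # -- stratum timeline transitions at cycle start
    if (t > 1L && kind_t != kind_prev) {
      if (kind_prev == "on" && kind_t == "holiday") {
        strata <- rbind(strata, data.frame(
          status = "holiday", m_on = fr$sched$months_on_start[t],
          off_ref = fr$sched$calendar_start[t]))
        new_id <- nrow(strata)
        sid[sid == .which_status(strata, "on")] <- new_id
        strata$status[strata$status == "on"] <- "retired_on"
      } else if (kind_prev == "holiday" && kind_t == "on") {
        hol <- which(strata$status == "holiday")
        strata$status[strata$status == "retired_on"] <- "on"
        on_id <- .which_status(strata, "on")
        for (h in hol) sid[sid == h] <- on_id
        strata$status[hol] <- "dead_stratum"
      } else if (kind_t == "off") {
        strata$status[strata$status == "holiday"] <- "disc"
        on_row <- which(strata$status == "on")
        if (length(on_row) == 1L) {
          strata$status[on_row] <- "disc"
          strata$m_on[on_row] <- fr$sched$months_on_start[t]
          strata$off_ref[on_row] <- fr$sched$calendar_start[t]
        }
      }
    }
    # -- merge fully offset discontinuation strata into a single off pool
    cal_t <- fr$sched$calendar_start[t]
    disc_rows <- which(strata$status == "disc")
    for (d in disc_rows) {
      T_eff <- min(strata$m_on[d], fr$max_offset_months)
      if (cal_t - strata$off_ref[d] >= T_eff) {
        off_id <- .which_status(strata, "off")
        if (is.na(off_id)) {
          strata <- rbind(strata, data.frame(status = "off", m_on = 0,
                                             off_ref = 0))
          off_id <- nrow(strata)
        }
        sid[sid == d] <- off_id
        strata$status[d] <- "dead_stratum"
      }
    }

    # -- persistence flow out of the on stratum
    if (kind_t == "on") {
      P_t <- fr$pers$persistent[t]
      flow_frac <- if (P_prev > 0) max(0, 1 - P_t / P_prev) else 0
      if (flow_frac > 1e-15) {
        strata <- rbind(strata, data.frame(
          status = "disc", m_on = fr$pers$months_on_at_disc[t],
          off_ref = fr$pers$off_ref[t]))
        new_id <- nrow(strata)
        on_id <- .which_status(strata, "on")
        on_rows <- which(sid == on_id)
        if (length(on_rows) > 0L) {
          st <- c(st, st[on_rows]); ck <- c(ck, ck[on_rows])
          fx <- c(fx, fx[on_rows]); vf <- c(vf, vf[on_rows])
          sid <- c(sid, rep(new_id, length(on_rows)))
          m <- c(m, m[on_rows] * flow_frac)
          m[on_rows] <- m[on_rows] * (1 - flow_frac)
        }
      }
      P_prev <- P_t
    }

    # -- per-stratum treatment RR matrix for this cycle
    n_str <- nrow(strata)
    tr_mat <- matrix(1, nrow = n_str, ncol = 4L,
                     dimnames = list(NULL, .SITES))
    for (k in seq_len(n_str)) {
      stt <- strata$status[k]
      if (stt == "on") {
        tr_mat[k, ] <- fr$eff_on[t, ]
      } else if (stt %in% c("disc", "holiday")) {
        r0 <- vapply(.SITES, function(s) {
          treatment_rr(params, strat$drug, s, strata$m_on[k])
        }, 0)
        mso_mid <- (cal_t + 3) - strata$off_ref[k]
        tr_mat[k, ] <- residual_rr(r0, strata$m_on[k], max(mso_mid, 0),
                                   strat$max_offset_years)
      }
    }

    # -- death (before fracture)
    rre <- .excess_rr(st, ck, vf, fr$rrx[t, "hip"], fr$rrx[t, "vertebral"],
                      fr$rrx[t, "other"], win)
    qd <- pmin(1, fr$q_cycle[t] * (1 + fr$att * (rre - 1)))
    deaths <- sum(m * qd)
    m <- m * (1 - qd)

    # -- site probabilities per compartment
    p <- sapply(seq_along(.SITES), function(j) {
      s <- .SITES[j]
      dis <- ifelse(fx == 1L, fr$dis1[t, s], fr$dis0[t, s])
      1 - exp(-0.5 * fr$g[t, s] * dis * tr_mat[cbind(sid, j)])
    })
    if (length(st) == 1L) p <- matrix(p, nrow = 1)
    ph <- p[, 1]; pv <- p[, 2]; pw <- p[, 3]; po <- p[, 4]

    # -- routing
    A <- st == 1L | st == 4L | st == 5L
    B <- st == 2L | st == 6L
    C <- st == 3L | st == 7L

    u_src <- fr$u_base[t] * .state_mult(st, ck, vf, fr$mult)

    o_st <- integer(0); o_ck <- integer(0); o_fx <- integer(0)
    o_vf <- integer(0); o_sid <- integer(0); o_m <- numeric(0)
    emit <- function(s2, c2, f2, v2, id2, m2) {
      keep <- m2 > 0
      o_st <<- c(o_st, s2[keep]); o_ck <<- c(o_ck, c2[keep])
      o_fx <<- c(o_fx, f2[keep]); o_vf <<- c(o_vf, v2[keep])
      o_sid <<- c(o_sid, id2[keep]); o_m <<- c(o_m, m2[keep])
    }

    ev <- c(hip = 0, vert = 0, wrist = 0, other = 0)
    ds <- c(vert = 0, wrist = 0, other = 0)
    ds_cost <- c(vert = 0, wrist = 0, other = 0)
    ds_disu <- 0

    if (any(A)) {
      mA <- m[A]
      pvv <- (1 - ph[A]) * pv[A]
      pw2 <- (1 - ph[A]) * (1 - pv[A]) * pw[A]
      po2 <- (1 - ph[A]) * (1 - pv[A]) * (1 - pw[A]) * po[A]
      pnone <- 1 - ph[A] - pvv - pw2 - po2
      n_A <- sum(A)
      emit(rep(2L, n_A), rep(0L, n_A), rep(1L, n_A), vf[A], sid[A], mA * ph[A])
      emit(rep(3L, n_A), rep(0L, n_A), rep(1L, n_A), rep(2L, n_A), sid[A],
           mA * pvv)
      emit(rep(4L, n_A), rep(0L, n_A), rep(1L, n_A), vf[A], sid[A], mA * pw2)
      emit(rep(5L, n_A), rep(0L, n_A), rep(1L, n_A), vf[A], sid[A], mA * po2)
      # no new fracture: advance the state clock
      stA <- st[A]; ckA <- ck[A]
      ns <- stA; nc <- ckA
      wl <- stA == 1L
      nc[wl] <- ifelse(ckA[wl] == 0L | ckA[wl] >= win - 1L, 0L, ckA[wl] + 1L)
      wr0 <- stA == 4L & ckA == 0L; nc[wr0] <- 1L
      wr1 <- stA == 4L & ckA == 1L; ns[wr1] <- 1L; nc[wr1] <- 0L
      ot0 <- stA == 5L & ckA == 0L; nc[ot0] <- 1L
      ot1 <- stA == 5L & ckA == 1L; ns[ot1] <- 1L
      nc[ot1] <- if (win > 2L) 2L else 0L
      emit(ns, nc, fx[A], vf[A], sid[A], mA * pnone)
      ev["hip"] <- ev["hip"] + sum(mA * ph[A])
      ev["vert"] <- ev["vert"] + sum(mA * pvv)
      ev["wrist"] <- ev["wrist"] + sum(mA * pw2)
      ev["other"] <- ev["other"] + sum(mA * po2)
    }
    if (any(B)) {
      mB <- m[B]
      n_B <- sum(B)
      emit(rep(2L, n_B), rep(0L, n_B), rep(1L, n_B), vf[B], sid[B], mB * ph[B])
      nc <- ifelse(st[B] == 2L, 1L, pmin(ck[B] + 1L, win))
      emit(rep(6L, n_B), nc, rep(1L, n_B), vf[B], sid[B], mB * (1 - ph[B]))
      ev["hip"] <- ev["hip"] + sum(mB * ph[B])
      dv <- sum(mB * pv[B]); dw <- sum(mB * pw[B]); do_ <- sum(mB * po[B])
      ds <- ds + c(vert = dv, wrist = dw, other = do_)
      ds_cost <- ds_cost + c(vert = dv * fr$costs$vertebral$y1[t],
                             wrist = dw * fr$costs$wrist$y1[t],
                             other = do_ * fr$costs$other$y1[t])
      ds_disu <- ds_disu +
        sum(mB * pv[B] * u_src[B]) * (1 - fr$mult$v1) +
        sum(mB * pw[B] * u_src[B]) * (1 - fr$mult$w1) +
        sum(mB * po[B] * u_src[B]) * (1 - fr$mult$o1)
    }
    if (any(C)) {
      mC <- m[C]
      n_C <- sum(C)
      emit(rep(2L, n_C), rep(0L, n_C), rep(1L, n_C), vf[C], sid[C], mC * ph[C])
      pvv <- (1 - ph[C]) * pv[C]
      emit(rep(3L, n_C), rep(0L, n_C), rep(1L, n_C), rep(2L, n_C), sid[C],
           mC * pvv)
      nc <- ifelse(st[C] == 3L, 1L, pmin(ck[C] + 1L, win))
      emit(rep(7L, n_C), nc, rep(1L, n_C), vf[C], sid[C],
           mC * (1 - ph[C]) * (1 - pv[C]))
      ev["hip"] <- ev["hip"] + sum(mC * ph[C])
      ev["vert"] <- ev["vert"] + sum(mC * pvv)
      dw <- sum(mC * pw[C]); do_ <- sum(mC * po[C])
      ds <- ds + c(vert = 0, wrist = dw, other = do_)
      ds_cost <- ds_cost + c(vert = 0,
                             wrist = dw * fr$costs$wrist$y1[t],
                             other = do_ * fr$costs$other$y1[t])
      ds_disu <- ds_disu +
        sum(mC * pw[C] * u_src[C]) * (1 - fr$mult$w1) +
        sum(mC * po[C] * u_src[C]) * (1 - fr$mult$o1)
    }

    # -- aggregate duplicate compartments
    radix <- win + 1L
    key <- (((o_sid * 3L + o_vf) * 2L + o_fx) * radix + o_ck) * 8L + o_st
    agg <- rowsum(o_m, key, reorder = TRUE)
    ukey <- as.integer(rownames(agg))
    m <- as.numeric(agg)
    st <- ukey %% 8L
    r <- ukey %/% 8L
    ck <- r %% radix
    r <- r %/% radix
    fx <- r %% 2L
    r <- r %/% 2L
    vf <- r %% 3L
    sid <- r %/% 3L
    if (any(m < 0)) stop("negative occupancy: engine invariant violated")

    # -- accrual on during-cycle occupancy
    cum_dead <- cum_dead + deaths
    alive <- sum(m)
    umult <- .state_mult(st, ck, vf, fr$mult)
    qaly_u <- sum(m * fr$u_base[t] * umult) * 0.5 - ds_disu
    state_cost <- .state_cost(st, ck, list(
      hip = list(y1 = fr$costs$hip$y1[t], y2 = fr$costs$hip$y2[t]),
      vertebral = list(y1 = fr$costs$vertebral$y1[t],
                       y2 = fr$costs$vertebral$y2[t]),
      wrist = list(y1 = fr$costs$wrist$y1[t]),
      other = list(y1 = fr$costs$other$y1[t])))
    site_of <- .state_site(st)
    c_hip <- sum(m[site_of == "hip"] * state_cost[site_of == "hip"], na.rm = TRUE)
    c_vert <- sum(m[site_of == "vertebral"] * state_cost[site_of == "vertebral"],
                  na.rm = TRUE) + ds_cost[["vert"]]
    c_wrist <- sum(m[site_of == "wrist"] * state_cost[site_of == "wrist"],
                   na.rm = TRUE) + ds_cost[["wrist"]]
    c_other <- sum(m[site_of == "other"] * state_cost[site_of == "other"],
                   na.rm = TRUE) + ds_cost[["other"]]
    on_id <- .which_status(strata, "on")
    mass_on <- if (is.na(on_id) || kind_t != "on") 0 else sum(m[sid == on_id])
    c_drug <- mass_on * fr$drug_only_cycle[t]
    c_mgmt <- mass_on * (fr$drug_cost_cycle[t] - fr$drug_only_cycle[t])
    c_ltc <- ev[["hip"]] * fr$ltc_per_event
    dfac <- fr$df[t]
    rec[t, ] <- c(alive, deaths, ev, ds,
                  c_drug * dfac, c_mgmt * dfac, c_hip * dfac, c_vert * dfac,
                  c_wrist * dfac, c_other * dfac, c_ltc * dfac,
                  qaly_u * dfac, alive * 0.5 * dfac,
                  c_drug, c_mgmt, c_hip, c_vert, c_wrist, c_other, c_ltc,
                  qaly_u)
    if (store_compartments) {
      comp_log[[t]] <- tibble::tibble(
        cycle = t - 1L, state = names(.ST)[st], clock = ck, prior_fx = fx,
        prior_vf = vf, stratum = strata$status[sid], mass = m)
    }
    if (abs(alive + cum_dead - 1) > 1e-10) {
      stop(sprintf("mass conservation violated at cycle %d: %.3e",
                   t - 1L, alive + cum_dead - 1))
    }
    if (alive < 1e-14) {
      rec <- rec[seq_len(t), , drop = FALSE]
      if (store_compartments) comp_log <- comp_log[seq_len(t)]
      break
    }
  }

  cycles <- tibble::as_tibble(rec)
  cycles$cycle <- seq_len(nrow(rec)) - 1L
  cycles$age <- cfg$start_age + 0.5 * cycles$cycle
  cycles$ly_u <- cycles$alive * 0.5
  cycles <- cycles[, c("cycle", "age", setdiff(names(cycles),
                                               c("cycle", "age")))]
  structure(
    list(cycles = cycles, strategy = strat, params_config = cfg,
         compartments = if (store_compartments) {
           dplyr::bind_rows(comp_log)
         } else NULL,
         final_alive = if (nrow(rec) > 0) rec[nrow(rec), "alive"] else 1),
    class = "osteo_trace"
  )
}

.which_status <- function(strata, status) {
  i <- which(strata$status == status)
  if (length(i) == 0L) NA_integer_ else i[[1L]]
}

#' @export
print.osteo_trace <- function(x, ...) {
  cat("<osteo_trace>", x$strategy$id, "-", nrow(x$cycles), "cycles\n")
  cat(sprintf("  events/patient: hip %.4f, vertebral %.4f, wrist %.4f, other %.4f\n",
              sum(x$cycles$ev_hip) + 0,
              sum(x$cycles$ev_vert) + sum(x$cycles$ds_vert),
              sum(x$cycles$ev_wrist) + sum(x$cycles$ds_wrist),
              sum(x$cycles$ev_other) + sum(x$cycles$ds_other)))
  cat(sprintf("  discounted LY %.3f, QALY %.3f\n",
              sum(x$cycles$ly), sum(x$cycles$qaly)))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' Writes one row per cycle x compartment (requires
#' `store_compartments = TRUE` in [run_trace()]), for debugging and
#' inspection.
#'
#' @param trace an `osteo_trace`.
#' @param file output CSV path.
#' @export
export_trace <- function(trace, file) {
  if (is.null(trace$compartments)) {
    stop("trace was run without store_compartments = TRUE", call. = FALSE)
  }
  readr::write_csv(trace$compartments, file)
  invisible(file)
}
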