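# Individual-level Monte Carlo oracle. Implements rule-for-rule the same
# cycle conventions as run_trace() (shared model_frame(); stratum timeline
# -> persistence discontinuation -> death -> fracture routing -> accrual on
# the post-transition state), with each individual carrying its own clocks.
# Its purpose is validation: cohort-engine expectations must agree with the
# simulated means within Monte Carlo error.

.S_NEVER <- 0L; .S_ON <- 1L; .S_HOL <- 2L; .S_DISC <- 3L; .S_OFF <- 4L

#' Microsimulation oracle
#'
#' Simulates `n` individual trajectories under the identical risk
#' composition, hierarchy routing, persistence/offset and accrual rules as
#' the cohort engine, and returns mean discounted cost, QALYs, life-years
#' and per-site fracture events with Monte Carlo standard errors.
#'
#' @param strat an `osteo_strategy`.
#' @param params an `osteo_params` object.
#' @param n number of simulated individuals.
#' @param seed RNG seed; fixed seed gives identical output across runs.
#' @return a list with tibbles `summary` (columns `metric`, `mean`, `se`)
#'   and the problem size `n`.
#' @export
#' @examples
#' simulate_cohort(strategy_no_treatment(), default_parameters(),
#'                 n = 500, seed = 1)$summary
simulate_cohort <- function(strat, params, n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  fr <- model_frame(strat, params)
  cfg <- params$config
  win <- fr$mort_window

  has_tx <- !is.na(strat$drug) && fr$n_cycles > 0L &&
    any(fr$sched$kind != "off")

  st <- rep(1L, n); ck <- rep(0L, n)
  vf <- as.integer(stats::runif(n) < cfg$prevalent_vf_fraction)
  fx <- vf
  status <- rep(if (has_tx) .S_ON else .S_NEVER, n)
  m_on <- rep(0, n); off_ref <- rep(0, n)
  alive <- rep(TRUE, n)

  cost <- numeric(n); qaly <- numeric(n); ly <- numeric(n)
  ev_hip <- numeric(n); ev_vert <- numeric(n)
  ev_wrist <- numeric(n); ev_other <- numeric(n)

  # per-individual residual/treatment RR for a site
  site_tr <- function(s, j, cal_t, t) {
    tr <- rep(1, n)
    on_i <- alive & status == .S_ON
    tr[on_i] <- fr$eff_on[t, j]
    res_i <- alive & (status == .S_DISC | status == .S_HOL)
    if (any(res_i)) {
      r0 <- treatment_rr(params, strat$drug, s, m_on[res_i])
      mso_mid <- pmax((cal_t + 3) - off_ref[res_i], 0)
      tr[res_i] <- residual_rr(r0, m_on[res_i], mso_mid,
                               strat$max_offset_years)
    }
    tr
  }

  P_prev <- 1
  for (t in seq_len(fr$n_cycles)) {
    if (!any(alive)) break
    kind_t <- fr$sched$kind[t]
    kind_prev <- if (t == 1L) kind_t else fr$sched$kind[t - 1L]
    cal_t <- fr$sched$calendar_start[t]

    if (t > 1L && kind_t != kind_prev) {
      if (kind_prev == "on" && kind_t == "holiday") {
        i <- status == .S_ON
        status[i] <- .S_HOL
        m_on[i] <- fr$sched$months_on_start[t]
        off_ref[i] <- cal_t
      } else if (kind_prev == "holiday" && kind_t == "on") {
        status[status == .S_HOL] <- .S_ON
      } else if (kind_t == "off") {
        i <- status == .S_ON
        status[i] <- .S_DISC
        m_on[i] <- fr$sched$months_on_start[t]
        off_ref[i] <- cal_t
        status[status == .S_HOL] <- .S_DISC
      }
    }
    done <- status == .S_DISC &
      (cal_t - off_ref) >= pmin(m_on, fr$max_offset_months)
    status[done] <- .S_OFF

    if (kind_t == "on") {
      P_t <- fr$pers$persistent[t]
      flow_frac <- if (P_prev > 0) max(0, 1 - P_t / P_prev) else 0
      if (flow_frac > 0) {
        leave <- alive & status == .S_ON & stats::runif(n) < flow_frac
        status[leave] <- .S_DISC
        m_on[leave] <- fr$pers$months_on_at_disc[t]
        off_ref[leave] <- fr$pers$off_ref[t]
      }
      P_prev <- P_t
    }

    # death before fracture
    rre <- .excess_rr(st, ck, vf, fr$rrx[t, "hip"], fr$rrx[t, "vertebral"],
                      fr$rrx[t, "other"], win)
    qd <- pmin(1, fr$q_cycle[t] * (1 + fr$att * (rre - 1)))
    dies <- alive & stats::runif(n) < qd
    alive[dies] <- FALSE
    if (!any(alive)) break

    p <- matrix(0, n, 4L)
    for (j in 1:4) {
      s <- .SITES[j]
      dis <- ifelse(fx == 1L, fr$dis1[t, s], fr$dis0[t, s])
      p[, j] <- 1 - exp(-0.5 * fr$g[t, s] * dis * site_tr(s, j, cal_t, t))
    }
    ph <- p[, 1]; pv <- p[, 2]; pw <- p[, 3]; po <- p[, 4]

    u1 <- stats::runif(n); u2 <- stats::runif(n)
    u3 <- stats::runif(n); u4 <- stats::runif(n)
    u_src <- fr$u_base[t] * .state_mult(st, ck, vf, fr$mult)
    dfac <- fr$df[t]

    A <- alive & (st == 1L | st == 4L | st == 5L)
    B <- alive & (st == 2L | st == 6L)
    C <- alive & (st == 3L | st == 7L)

    ds_disu_i <- numeric(n)   # downstream disutility this cycle
    ds_cost_i <- numeric(n)   # downstream cost this cycle
    hip_event <- rep(FALSE, n)

    # group A: well / wrist / other convalescent - full routing by winner
    hitA_h <- A & u1 < ph
    hitA_v <- A & !hitA_h & u2 < pv
    hitA_w <- A & !hitA_h & !hitA_v & u3 < pw
    hitA_o <- A & !hitA_h & !hitA_v & !hitA_w & u4 < po
    noneA <- A & !hitA_h & !hitA_v & !hitA_w & !hitA_o

    # group B: hip acute / post hip - hip re-fracture routes, rest downstream
    hitB_h <- B & u1 < ph
    dsB_v <- B & u2 < pv
    dsB_w <- B & u3 < pw
    dsB_o <- B & u4 < po

    # group C: vertebral acute / post vert - hip and vert route
    hitC_h <- C & u1 < ph
    hitC_v <- C & !hitC_h & u2 < pv
    dsC_w <- C & u3 < pw
    dsC_o <- C & u4 < po

    ev_hip <- ev_hip + (hitA_h | hitB_h | hitC_h)
    ev_vert <- ev_vert + (hitA_v | hitC_v) + dsB_v
    ev_wrist <- ev_wrist + hitA_w + dsB_w + dsC_w
    ev_other <- ev_other + hitA_o + dsB_o + dsC_o

    ds_cost_i <- ds_cost_i +
      dsB_v * fr$costs$vertebral$y1[t] +
      (dsB_w + dsC_w) * fr$costs$wrist$y1[t] +
      (dsB_o + dsC_o) * fr$costs$other$y1[t]
    ds_disu_i <- ds_disu_i +
      dsB_v * u_src * (1 - fr$mult$v1) +
      (dsB_w + dsC_w) * u_src * (1 - fr$mult$w1) +
      (dsB_o + dsC_o) * u_src * (1 - fr$mult$o1)
    hip_event <- hitA_h | hitB_h | hitC_h

    # routing / clock advance
    ns <- st; nc <- ck
    hit_h <- hitA_h | hitB_h | hitC_h
    ns[hit_h] <- 2L; nc[hit_h] <- 0L
    hit_v <- hitA_v | hitC_v
    ns[hit_v] <- 3L; nc[hit_v] <- 0L
    ns[hitA_w] <- 4L; nc[hitA_w] <- 0L
    ns[hitA_o] <- 5L; nc[hitA_o] <- 0L
    fx[hit_h | hit_v | hitA_w | hitA_o] <- 1L
    vf[hit_v] <- 2L

    adv_none <- noneA
    wl <- adv_none & st == 1L
    nc[wl] <- ifelse(ck[wl] == 0L | ck[wl] >= win - 1L, 0L, ck[wl] + 1L)
    wr0 <- adv_none & st == 4L & ck == 0L; nc[wr0] <- 1L
    wr1 <- adv_none & st == 4L & ck == 1L; ns[wr1] <- 1L; nc[wr1] <- 0L
    ot0 <- adv_none & st == 5L & ck == 0L; nc[ot0] <- 1L
    ot1 <- adv_none & st == 5L & ck == 1L; ns[ot1] <- 1L
    nc[ot1] <- if (win > 2L) 2L else 0L

    advB <- B & !hitB_h
    nc[advB] <- ifelse(st[advB] == 2L, 1L, pmin(ck[advB] + 1L, win))
    ns[advB] <- 6L
    advC <- C & !hitC_h & !hitC_v
    nc[advC] <- ifelse(st[advC] == 3L, 1L, pmin(ck[advC] + 1L, win))
    ns[advC] <- 7L
    st <- ns; ck <- nc

    # accrual on post-transition occupancy (survivors only)
    ly[alive] <- ly[alive] + 0.5 * dfac
    umult <- .state_mult(st, ck, vf, fr$mult)
    qaly[alive] <- qaly[alive] +
      (fr$u_base[t] * umult[alive] * 0.5 - ds_disu_i[alive]) * dfac
    sc <- .state_cost(st, ck, list(
      hip = list(y1 = fr$costs$hip$y1[t], y2 = fr$costs$hip$y2[t]),
      vertebral = list(y1 = fr$costs$vertebral$y1[t],
                       y2 = fr$costs$vertebral$y2[t]),
      wrist = list(y1 = fr$costs$wrist$y1[t]),
      other = list(y1 = fr$costs$other$y1[t])))
    drug_i <- (alive & status == .S_ON & kind_t == "on") * fr$drug_cost_cycle[t]
    cost[alive] <- cost[alive] +
      (sc[alive] + ds_cost_i[alive] +
         hip_event[alive] * fr$ltc_per_event + drug_i[alive]) * dfac
  }

  msd <- function(x) c(mean(x), stats::sd(x) / sqrt(n))
  out <- rbind(cost = msd(cost), qaly = msd(qaly), ly = msd(ly),
               ev_hip = msd(ev_hip), ev_vert = msd(ev_vert),
               ev_wrist = msd(ev_wrist), ev_other = msd(ev_other))
  list(summary = tibble::tibble(metric = rownames(out), mean = out[, 1],
                                se = out[, 2]),
       n = n)
}
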