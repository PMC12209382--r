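# Probabilistic sensitivity analysis: joint sampling of all uncertain
# inputs, common random numbers across strategies within a draw, CEACs.

# Beta parameters matched to (mean, sd); sd clipped when incompatible.
.beta_draw <- function(n, mean, sd) {
  if (sd <= 0 || mean <= 0 || mean >= 1) return(rep(mean, n))
  vmax <- mean * (1 - mean)
  if (sd^2 >= vmax) {
    warning("beta moment-matching: variance clipped", call. = FALSE)
    sd <- sqrt(0.9 * vmax)
  }
  nu <- vmax / sd^2 - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

# Lognormal with mean = point estimate (moment-matched, not median).
.lnorm_draw <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sig2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - sig2 / 2, sdlog = sqrt(sig2))
}

#' Sample one probabilistic parameter set
#'
#' Treatment-efficacy RRs are lognormal (mean equal to the point estimate,
#' SE 10% of it unless supplied); persistence proportions, utilities and
#' the long-term-care admission probability are beta (moment-matched);
#' fracture costs are normal truncated at zero. Sampled persistence values
#' are forced nonincreasing (running minimum) so the curve stays a valid
#' survival-type function.
#'
#' @param params base `osteo_params`.
#' @param se_fraction standard error as a fraction of the point estimate
#'   (default 0.10). Zero makes every distribution degenerate.
#' @return a new `osteo_params` draw.
#' @export
sample_parameters <- function(params, se_fraction = 0.10) {
  p <- unclass(params)
  p$efficacy$rr <- pmin(vapply(p$efficacy$rr, function(x) {
    .lnorm_draw(1, x, se_fraction)
  }, 0), 1.5)
  for (d in unique(p$persistence$drug)) {
    i <- which(p$persistence$drug == d)
    i <- i[order(p$persistence$month[i])]
    vals <- p$persistence$p[i]
    vals[-1] <- vapply(vals[-1], function(x) {
      .beta_draw(1, x, se_fraction * x)
    }, 0)
    p$persistence$p[i] <- cummin(pmin(vals, 1))
  }
  p$utilities$baseline$utility <- vapply(p$utilities$baseline$utility,
                                         function(x) .beta_draw(1, x, se_fraction * x), 0)
  p$utilities$multiplier$mult <- vapply(p$utilities$multiplier$mult,
                                        function(x) .beta_draw(1, x, se_fraction * x), 0)
  p$costs$fracture$cost <- vapply(p$costs$fracture$cost, function(x) {
    if (se_fraction <= 0) x else max(0, stats::rnorm(1, x, se_fraction * x))
  }, 0)
  # keep the chronic <= acute cost invariant under sampling
  fc <- p$costs$fracture
  for (s in c("hip", "vertebral")) {
    for (b in unique(fc$age_band)) {
      i1 <- fc$site == s & fc$age_band == b & fc$year == "1"
      i2 <- fc$site == s & fc$age_band == b & fc$year == "2plus"
      if (any(i2)) {
        fc$cost[i2] <- pmin(fc$cost[i2], fc$cost[i1])
      }
    }
  }
  p$costs$fracture <- fc
  p$costs$ltc_admission_prob_after_hip <-
    .beta_draw(1, p$costs$ltc_admission_prob_after_hip,
               se_fraction * p$costs$ltc_admission_prob_after_hip)
  validate_parameters(structure(p, class = "osteo_params"))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` probabilistic parameter sets, evaluates every strategy on the
#' common draw (common random numbers keep the incremental comparisons
#' low-noise), and derives cost-effectiveness acceptability curves for the
#' first strategy against each comparator: the proportion of draws in which
#' `threshold x dQALY - dcost >= 0`.
#'
#' @param params base `osteo_params`.
#' @param n number of probabilistic iterations (default 1000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param strategies list of strategies; first is the intervention.
#' @param thresholds willingness-to-pay grid, USD/QALY.
#' @param se_fraction forwarded to [sample_parameters()].
#' @return an object of class `osteo_psa`: `draws` (tibble: draw, strategy,
#'   cost, qaly), `ceac` (tibble: comparator, threshold, prob), `n`, `seed`.
#' @export
psa <- function(params, n = 1000, seed = 1,
                strategies = list(strategy_denosumab(),
                                  strategy_no_treatment(),
                                  strategy_alendronate()),
                thresholds = seq(0, 300000, by = 5000),
                se_fraction = 0.10) {
  stopifnot(n >= 1)
  set.seed(seed)
  ids <- vapply(strategies, function(s) s$id, "")
  draws <- vector("list", n)
  for (k in seq_len(n)) {
    pk <- sample_parameters(params, se_fraction)
    res <- purrr::map_dfr(strategies, evaluate_strategy, params = pk)
    draws[[k]] <- tibble::tibble(draw = k, strategy = res$strategy,
                                 cost = res$cost_total, qaly = res$qaly)
  }
  draws <- dplyr::bind_rows(draws)
  base <- draws[draws$strategy == ids[1], ]
  ceac <- purrr::map_dfr(ids[-1], function(cmp) {
    comp <- draws[draws$strategy == cmp, ]
    dc <- base$cost - comp$cost
    dq <- base$qaly - comp$qaly
    purrr::map_dfr(thresholds, function(lam) {
      tibble::tibble(comparator = cmp, threshold = lam,
                     prob = mean(lam * dq - dc >= 0))
    })
  })
  structure(list(draws = draws, ceac = ceac, n = n, seed = seed,
                 intervention = ids[1]),
            class = "osteo_psa")
}

#' @export
print.osteo_psa <- function(x, ...) {
  cat("<osteo_psa>", x$n, "draws, intervention", x$intervention, "\n")
  print(glance(x))
  invisible(x)
}

#' @rdname psa
#' @param x an `osteo_psa` object.
#' @param ... unused.
#' @export
tidy.osteo_psa <- function(x, ...) {
  base <- x$draws[x$draws$strategy == x$intervention, ]
  others <- unique(x$draws$strategy[x$draws$strategy != x$intervention])
  purrr::map_dfr(others, function(cmp) {
    comp <- x$draws[x$draws$strategy == cmp, ]
    tibble::tibble(draw = base$draw, comparator = cmp,
                   delta_cost = base$cost - comp$cost,
                   delta_qaly = base$qaly - comp$qaly)
  })
}

#' @rdname psa
#' @export
glance.osteo_psa <- function(x, ...) {
  pr <- function(cmp, lam) {
    cc <- x$ceac
    row <- cc[cc$comparator == cmp & cc$threshold == lam, ]
    if (nrow(row) == 1) row$prob else NA_real_
  }
  others <- unique(x$ceac$comparator)
  purrr::map_dfr(others, function(cmp) {
    tibble::tibble(comparator = cmp, n = x$n,
                   prob_ce_100k = pr(cmp, 100000),
                   prob_ce_150k = pr(cmp, 150000))
  })
}

#' Plot PSA results
#'
#' `autoplot()` on an `osteo_psa` gives the incremental cost-effectiveness
#' scatter; [plot_ceac()] the acceptability curves.
#'
#' @param object an `osteo_psa`.
#' @param ... unused.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @export
#' @method autoplot osteo_psa
autoplot.osteo_psa <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$delta_qaly,
                                   y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~comparator) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = paste(object$intervention, "vs comparators"))
}

#' @rdname autoplot.osteo_psa
#' @param x an `osteo_psa`.
#' @export
plot_ceac <- function(x) {
  ggplot2::ggplot(x$ceac, ggplot2::aes(x = .data$threshold, y = .data$prob,
                                       colour = .data$comparator)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "P(cost-effective)",
                  title = paste("CEAC:", x$intervention))
}

#' Plot a cohort trace
#'
#' Survival and cumulative fracture burden over the model horizon.
#'
#' @param object an `osteo_trace`.
#' @param ... unused.
#' @export
#' @method autoplot osteo_trace
autoplot.osteo_trace <- function(object, ...) {
  cy <- object$cycles
  df <- tibble::tibble(
    age = rep(cy$age, 2),
    value = c(cy$alive, cumsum(cy$ev_hip + cy$ev_vert + cy$ds_vert +
                                 cy$ev_wrist + cy$ds_wrist +
                                 cy$ev_other + cy$ds_other)),
    series = rep(c("alive", "cumulative fractures"), each = nrow(cy))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "Age (years)", y = NULL, title = object$strategy$id)
}
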