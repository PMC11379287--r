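# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis: Beta distributions for utilities and probabilities,
# Gamma for costs, Monte Carlo propagation through the cohort engine, and
# cost-effectiveness acceptability curves.

#' Fit a Beta distribution from a point estimate and a range
#'
#' Method-of-moments fit with mean equal to the point estimate and standard
#' deviation \code{(high - low)/3.92} (the range is read as a 95\%
#' interval): \code{alpha = m(m(1-m)/v - 1)}, \code{beta = alpha(1-m)/m}.
#' If the implied variance is infeasible (point at 0 or 1, or variance
#' at least \code{m(1-m)}) a degenerate \code{fixed} spec is returned.
#'
#' @param point Mean, in [0, 1].
#' @param low,high Range bounds, \code{0 <= low <= point <= high <= 1},
#'   \code{low < high}.
#' @return A \code{dist_spec}: list with \code{family}, \code{point},
#'   \code{low}, \code{high}, \code{sd}, and shape parameters
#'   \code{alpha}, \code{beta}.
#' @export
fit_beta <- function(point, low, high) {
  if (!(0 <= low && low <= point && point <= high && high <= 1))
    stop("need 0 <= low <= point <= high <= 1")
  if (!(low < high)) stop("need low < high")
  s <- (high - low) / 3.92
  v <- s^2
  if (point <= 0 || point >= 1 || v >= point * (1 - point))
    return(structure(list(family = "fixed", point = point, low = low,
                          high = high, sd = 0),
                     class = "dist_spec"))
  alpha <- point * (point * (1 - point) / v - 1)
  beta <- alpha * (1 - point) / point
  structure(list(family = "beta", point = point, low = low, high = high,
                 sd = s, alpha = alpha, beta = beta),
            class = "dist_spec")
}

#' Fit a Gamma distribution from a mean and standard deviation
#'
#' \code{shape = (mean/sd)^2}, \code{scale = sd^2/mean}; the fitted mean and
#' SD equal the inputs exactly.
#'
#' @param point Mean (> 0).
#' @param sd Standard deviation (> 0).
#' @return A \code{dist_spec} with \code{shape} and \code{scale}.
#' @export
fit_gamma <- function(point, sd) {
  stopifnot(point > 0, sd > 0)
  structure(list(family = "gamma", point = point, sd = sd,
                 low = max(0, point - 1.96 * sd), high = point + 1.96 * sd,
                 shape = (point / sd)^2, scale = sd^2 / point),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec>", x$family, "mean", format(x$point))
  if (x$family == "beta") cat(sprintf(" (a=%.3f, b=%.3f)", x$alpha, x$beta))
  if (x$family == "gamma") cat(sprintf(" (shape=%.3f, scale=%.5f)",
                                       x$shape, x$scale))
  cat("\n")
  invisible(x)
}

#' Analytic mean and SD of a fitted distribution
#'
#' @param spec A \code{dist_spec}.
#' @return Named numeric \code{(mean, sd)}.
#' @export
dist_moments <- function(spec) {
  switch(spec$family,
    fixed = c(mean = spec$point, sd = 0),
    beta = {
      a <- spec$alpha; b <- spec$beta
      c(mean = a / (a + b),
        sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = c(mean = spec$shape * spec$scale,
              sd = sqrt(spec$shape) * spec$scale),
    stop("unknown family"))
}

#' Draw from a fitted distribution
#'
#' @param spec A \code{dist_spec}.
#' @param n Number of draws.
#' @return Numeric vector (uses the current RNG state).
#' @export
draw_dist <- function(spec, n) {
  switch(spec$family,
    fixed = rep(spec$point, n),
    beta = rbeta(n, spec$alpha, spec$beta),
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
    stop("unknown family"))
}

#' Distribution registry for the uncertain parameters
#'
#' Fits one \code{dist_spec} per row of \code{P$uncertainty}: Beta for
#' probabilities and utilities (range read as a 95\% interval), Gamma for
#' costs (SD recovered from the recorded mean +/- 1.96 SD range).
#'
#' @param P A \code{drt_parameters} object.
#' @param fixed Collapse every distribution to its point value (degenerate
#'   registry, used for regression checks).
#' @return Named list of \code{dist_spec} objects.
#' @export
dist_registry <- function(P, fixed = FALSE) {
  un <- P$uncertainty
  specs <- list()
  for (i in seq_len(nrow(un))) {
    nm <- un$parameter[i]
    pt <- P[[nm]]
    specs[[nm]] <- if (fixed || un$high[i] <= un$low[i]) {
      structure(list(family = "fixed", point = pt, low = un$low[i],
                     high = un$high[i], sd = 0), class = "dist_spec")
    } else if (un$family[i] == "gamma") {
      fit_gamma(pt, (un$high[i] - un$low[i]) / 3.92)
    } else {
      fit_beta(pt, un$low[i], un$high[i])
    }
  }
  specs
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each parameter with an uncertainty range, re-runs both strategy arms
#' with that parameter at its low and at its high value (all others at
#' baseline) and records the resulting ICER (or incremental NMB). Entries
#' are sorted by descending spread, ties broken by parameter name.
#'
#' @param P A \code{drt_parameters} object.
#' @param wtp Willingness-to-pay used for the NMB metric and decision
#'   columns; defaults to the threshold implied by \code{P}.
#' @param metric \code{"icer"} (default) or \code{"nmb"} (incremental net
#'   monetary benefit, stable across dominance quadrants).
#' @param ... Passed to \code{\link{run_cohort}} (e.g. \code{horizon}).
#' @return A data frame (class \code{drt_tornado}): \code{parameter},
#'   \code{low}, \code{high}, \code{icer_at_low}, \code{icer_at_high} (or
#'   NMB columns), \code{spread}; baseline value in the \code{baseline}
#'   attribute.
#' @export
one_way_dsa <- function(P, wtp = NULL, metric = c("icer", "nmb"), ...) {
  metric <- match.arg(metric)
  if (is.null(wtp)) wtp <- wtp_threshold(P$gdp_per_capita, P$wtp_multiplier)
  un <- P$uncertainty
  if (!nrow(un)) stop("no parameter has an uncertainty range")

  eval_at <- function(Pmod) {
    res <- run_strategies(Pmod, trace = FALSE, ...)
    ic <- icer(res$TEST, res$NO_TEST, wtp)
    if (metric == "icer") ic$icer
    else wtp * ic$delta_effect - ic$delta_cost
  }
  base_val <- eval_at(P)

  rows <- lapply(seq_len(nrow(un)), function(i) {
    nm <- un$parameter[i]
    at <- function(v) {
      ov <- list(v); names(ov) <- nm
      eval_at(apply_overrides(P, ov, validate = FALSE))
    }
    v_lo <- if (un$low[i] == P[[nm]]) base_val else at(un$low[i])
    v_hi <- if (un$high[i] == P[[nm]]) base_val else at(un$high[i])
    data.frame(parameter = nm, low = un$low[i], high = un$high[i],
               value_at_low = v_lo, value_at_high = v_hi,
               spread = abs(v_hi - v_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), ]
  rownames(out) <- NULL
  names(out)[names(out) == "value_at_low"] <- paste0(metric, "_at_low")
  names(out)[names(out) == "value_at_high"] <- paste0(metric, "_at_high")
  attr(out, "baseline") <- base_val
  attr(out, "metric") <- metric
  attr(out, "wtp") <- wtp
  class(out) <- c("drt_tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation: each draw samples every uncertain parameter from
#' its fitted distribution, rebuilds the parameter set (transition-table
#' scalars rebalance \code{p_remain}; rows forced stochastic), and runs both
#' strategies through the deterministic cohort engine, recording the
#' incremental cost and effect. Draws where a transition row had to be
#' renormalized are counted; more than 1\% of them is an error.
#'
#' @param P A \code{drt_parameters} object.
#' @param n_draws Number of Monte Carlo repetitions (default 10,000).
#' @param seed RNG seed; the result is reproducible given the seed.
#' @param registry Optional registry from \code{\link{dist_registry}}
#'   (e.g. a degenerate \code{fixed = TRUE} one).
#' @param ... Passed to \code{\link{run_cohort}}.
#' @return A \code{psa_result}: \code{draws} data frame
#'   (\code{delta_cost}, \code{delta_effect}), \code{samples} matrix of
#'   sampled parameter values, \code{seed}, \code{n_draws},
#'   \code{n_renormalized}.
#' @export
run_psa <- function(P, n_draws = 10000, seed = 1L, registry = NULL, ...) {
  stopifnot(n_draws >= 1)
  n_draws <- as.integer(n_draws)
  if (is.null(registry)) registry <- dist_registry(P)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  nms <- names(registry)
  samples <- matrix(NA_real_, n_draws, length(nms),
                    dimnames = list(NULL, nms))
  for (nm in nms) samples[, nm] <- draw_dist(registry[[nm]], n_draws)

  dc <- de <- numeric(n_draws)
  n_renorm <- 0L
  for (d in seq_len(n_draws)) {
    ov <- as.list(samples[d, ])
    Pd <- apply_overrides(P, ov, validate = FALSE)
    n_renorm <- n_renorm + (attr(Pd, "renormalized") %||% 0L)
    res <- run_strategies(Pd, trace = FALSE, ...)
    dc[d] <- res$TEST$total_discounted_cost - res$NO_TEST$total_discounted_cost
    de[d] <- res$TEST$total_discounted_qaly - res$NO_TEST$total_discounted_qaly
  }
  if (n_renorm > 0.01 * n_draws)
    stop(sprintf("%d of %d draws required transition-row renormalization",
                 n_renorm, n_draws))
  structure(list(draws = data.frame(draw = seq_len(n_draws),
                                    delta_cost = dc, delta_effect = de),
                 samples = samples, seed = seed, n_draws = n_draws,
                 n_renormalized = n_renorm),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result> %d draws (seed %s): mean dCost %.2f, mean dQALY %.6f\n",
    x$n_draws, format(x$seed), mean(x$draws$delta_cost),
    mean(x$draws$delta_effect)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive incremental net monetary benefit
#' (\code{wtp * delta_effect - delta_cost > 0}).
#'
#' @param psa A \code{psa_result}.
#' @param wtp_grid Thresholds to evaluate (default 0 to 100,000 USD/QALY in
#'   steps of 1,000).
#' @return Data frame (class \code{drt_ceac}): \code{wtp},
#'   \code{prob_cost_effective}.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$draws) >= 1)
  de <- psa$draws$delta_effect
  dc <- psa$draws$delta_cost
  prob <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, prob_cost_effective = prob)
  class(out) <- c("drt_ceac", "data.frame")
  out
}
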