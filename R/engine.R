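# Deterministic cohort engine. The three clinical states (HIV, AIDS, death)
# are expanded into an extended space: stage x treatment state x first-line
# regimen x transmitted-resistance class. Treatment states:
#   S1  suppressed on the first line
#   F1  failed the first line (switches to the PI line the following cycle,
#       with a resistance test charged at the switch)
#   S2  suppressed on the second (PI) line
#   F2  failed the second line (persistent failure; no further switches)
# Opportunistic infection is redrawn each cycle for AIDS-stage occupants, so
# it enters as a within-cycle split rather than a carried state.

#' Discount factor for an annual cycle
#'
#' Cycle 0 (the first model year) is undiscounted; cycle \eqn{t} is weighted
#' \eqn{(1+r)^{-t}}.
#'
#' @param cycle_index Non-negative integer cycle (vectorized).
#' @param rate Annual discount rate (>= 0).
#' @return Numeric discount factor(s).
#' @examples
#' discount_factor(0, 0.03)  # 1
#' discount_factor(1, 0.03)  # 0.9708738
#' @export
discount_factor <- function(cycle_index, rate) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  if (rate < 0) stop("rate must be >= 0")
  (1 + rate)^(-cycle_index)
}

# Build the per-branch initial conditions of a strategy arm: one branch per
# (transmitted class x adverse-event outcome) with positive mass.
.build_branches <- function(strategy, P) {
  w_class <- c(none = 1 - P$tdr_nrti - P$tdr_pi - P$tdr_insti,
               NRTI = P$tdr_nrti, PI = P$tdr_pi, INSTI = P$tdr_insti)
  if (any(w_class < 0)) stop("transmitted prevalences exceed 1")
  branches <- list()
  for (cls in names(w_class)) {
    w <- w_class[[cls]]
    if (w <= 0) next
    a0 <- assign_initial_regimen(cls, strategy, P)
    if (a0$regimen == "DTG" && P$adverse_event_prob > 0) {
      ae <- apply_adverse_event(a0, cls, strategy, P)
      branches[[length(branches) + 1L]] <- list(
        class = cls, weight = w * (1 - P$adverse_event_prob),
        regimen1 = a0$regimen, eff1 = a0$effectiveness,
        entry_cost = a0$one_time_cost, informed = a0$informed)
      branches[[length(branches) + 1L]] <- list(
        class = cls, weight = w * P$adverse_event_prob,
        regimen1 = ae$regimen, eff1 = ae$effectiveness,
        entry_cost = a0$one_time_cost, informed = a0$informed)
    } else {
      branches[[length(branches) + 1L]] <- list(
        class = cls, weight = w,
        regimen1 = a0$regimen, eff1 = a0$effectiveness,
        entry_cost = a0$one_time_cost, informed = a0$informed)
    }
  }
  branches
}

#' Expected one-cycle transition of an extended state
#'
#' Looks up the published transition row for the state's clinical context and
#' age band and returns the expected distribution of next-cycle mass over
#' \code{remain} (same stage), \code{transition} (HIV to AIDS progression, or
#' AIDS to HIV re-suppression), and \code{death}. For AIDS-stage states the
#' within-cycle OI split (13\% if suppressed, 53\% if failed) mixes the
#' no-OI and with-OI rows.
#'
#' @param state List with \code{stage} (\code{"HIV"} or \code{"AIDS"}) and
#'   \code{suppression} (\code{"suppressed"} or \code{"failed"}).
#' @param age Current age in years.
#' @param P A \code{drt_parameters} object.
#' @return Named probability vector \code{(remain, transition, death)}
#'   summing to 1.
#' @export
transition_row_for <- function(state, age, P) {
  stage <- match.arg(state$stage, c("HIV", "AIDS"))
  supp <- match.arg(state$suppression, c("suppressed", "failed"))
  if (stage == "HIV") {
    .tt_row(P, if (supp == "suppressed") "hiv_suppressed" else "hiv_failed",
            age)
  } else {
    p_oi <- oi_probability(supp, P)
    (1 - p_oi) * .tt_row(P, "aids_no_oi", age) +
      p_oi * .tt_row(P, "aids_oi", age)
  }
}

#' Run the deterministic cohort model for one strategy
#'
#' Iterates the expected cohort distribution over annual cycles. Entry mixes
#' the diagnosis stage (82.3\% HIV / 17.7\% AIDS) and transmitted-resistance
#' classes; the first-line regimen and its suppression probability come from
#' the arm's decision rules; the 5\% dolutegravir adverse-event switch is a
#' first-cycle branch; first-line failures switch to the PI line one cycle
#' later with a resistance test charged and effectiveness marginalized over
#' acquired resistance. Costs and QALYs are accumulated per cycle and
#' discounted with \code{\link{discount_factor}}.
#'
#' @param strategy A \code{\link{strategy_spec}} (or \code{"TEST"} /
#'   \code{"NO_TEST"}).
#' @param P A \code{drt_parameters} object.
#' @param horizon Number of annual cycles (default: \code{P$horizon_years}).
#' @param start_age Cohort age at diagnosis (default: cohort mean age).
#' @param half_cycle Apply the standard half-cycle correction to
#'   state-membership rewards (half weight on the first cycle plus a
#'   discounted terminal half-cycle); one-time test costs are never halved.
#'   Default \code{FALSE}.
#' @param trace Build the full cohort trace (set \code{FALSE} for speed in
#'   sensitivity analyses).
#' @return A \code{ce_outcome}: list with \code{total_discounted_cost},
#'   \code{total_discounted_qaly}, undiscounted totals, and (if requested) a
#'   \code{trace} with per-state occupancies and per-cycle increments.
#' @export
run_cohort <- function(strategy, P, horizon = P$horizon_years,
                       start_age = P$cohort$mean_age,
                       half_cycle = FALSE, trace = TRUE) {
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  stopifnot(inherits(strategy, "drt_strategy"))
  if (horizon < 1) stop("horizon must be >= 1")
  rate <- P$discount_rate
  e2 <- post_failure_effectiveness(P)
  branches <- .build_branches(strategy, P)
  tabs <- .sim_tables(P)  # transition rows and care costs, indexed once

  # state matrices per branch: rows stage (HIV, AIDS), cols (S1, F1, S2, F2)
  M <- lapply(branches, function(b) {
    m <- matrix(0, 2L, 4L)
    m[1L, 1L] <- P$p_hiv_at_dx * b$eff1
    m[1L, 2L] <- P$p_hiv_at_dx * (1 - b$eff1)
    m[2L, 1L] <- P$p_aids_at_dx * b$eff1
    m[2L, 2L] <- P$p_aids_at_dx * (1 - b$eff1)
    m * b$weight
  })
  dead <- 0

  n_cyc <- as.integer(horizon)
  cost_inc <- qaly_inc <- numeric(n_cyc)
  onetime_inc <- numeric(n_cyc)       # test costs, exempt from half-cycle
  trace_rows <- if (trace) vector("list", n_cyc) else NULL

  u_hiv <- P$util_hiv
  p_oi_s <- P$oi_prob_success
  p_oi_f <- P$oi_prob_failure
  u_aids_s <- (1 - p_oi_s) * P$util_aids_no_oi + p_oi_s * P$util_aids_oi
  u_aids_f <- (1 - p_oi_f) * P$util_aids_no_oi + p_oi_f * P$util_aids_oi

  # per-branch care-cost vectors over treatment states (S1, F1, S2, F2),
  # for HIV/AIDS stage and first/subsequent year
  bcosts <- lapply(branches, function(b) {
    reg <- c(b$regimen1, b$regimen1, "PI", "PI")
    list(H = tabs$costs[paste0(reg, ".HIV"), , drop = FALSE],
         A = tabs$costs[paste0(reg, ".AIDS"), , drop = FALSE])
  })
  u_aids_vec <- c(u_aids_s, u_aids_f, u_aids_s, u_aids_f)

  cycle_rewards <- function(t) {
    # continuous (state-membership) rewards of the current occupancy
    yr <- if (t == 0L) 1L else 2L
    cost <- 0; qaly <- 0
    for (k in seq_along(branches)) {
      m <- M[[k]]
      cost <- cost + sum(m[1L, ] * bcosts[[k]]$H[, yr]) +
        sum(m[2L, ] * bcosts[[k]]$A[, yr])
      qaly <- qaly + sum(m[1L, ]) * u_hiv + sum(m[2L, ] * u_aids_vec)
    }
    c(cost, qaly)
  }

  for (t in seq_len(n_cyc) - 1L) {
    # failure-triggered switch takes effect the cycle after failure
    if (t > 0L) {
      for (k in seq_along(M)) {
        f1 <- M[[k]][, 2L]
        if (sum(f1) > 0) {
          onetime_inc[t + 1L] <- onetime_inc[t + 1L] + P$cost_drt * sum(f1)
          M[[k]][, 3L] <- M[[k]][, 3L] + e2 * f1
          M[[k]][, 4L] <- M[[k]][, 4L] + (1 - e2) * f1
          M[[k]][, 2L] <- 0
        }
      }
    } else {
      entry <- sum(vapply(branches, function(b) b$entry_cost * b$weight,
                          numeric(1)))
      onetime_inc[1L] <- onetime_inc[1L] + entry
    }

    rw <- cycle_rewards(t)
    cost_inc[t + 1L] <- rw[1L]
    qaly_inc[t + 1L] <- rw[2L]

    if (trace) {
      rows <- lapply(seq_along(branches), function(k) {
        b <- branches[[k]]; m <- M[[k]]
        data.frame(
          cycle = t,
          stage = rep(c("HIV", "AIDS"), 4L),
          suppression = rep(c("suppressed", "failed",
                              "suppressed", "failed"), each = 2L),
          line = rep(c(1L, 1L, 2L, 2L), each = 2L),
          regimen = rep(c(b$regimen1, b$regimen1, "PI", "PI"), each = 2L),
          resistance = b$class,
          informed = b$informed,
          occupancy = as.vector(m))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = t, stage = "DEATH", suppression = NA_character_,
        line = NA_integer_, regimen = NA_character_,
        resistance = NA_character_, informed = NA, occupancy = dead)
      trace_rows[[t + 1L]] <- do.call(rbind, rows)
    }

    # stage transitions at the end of the cycle; rows vectorized over the
    # treatment states (suppressed, failed, suppressed, failed)
    band <- .band_index(start_age + t)
    Rs <- tabs$raw[1L, band, ]
    Rf <- tabs$raw[2L, band, ]
    An <- tabs$raw[3L, band, ]
    Ao <- tabs$raw[4L, band, ]
    As <- (1 - p_oi_s) * An + p_oi_s * Ao
    Af <- (1 - p_oi_f) * An + p_oi_f * Ao
    rh_rem <- c(Rs[1L], Rf[1L], Rs[1L], Rf[1L])
    rh_tra <- c(Rs[2L], Rf[2L], Rs[2L], Rf[2L])
    rh_dth <- c(Rs[3L], Rf[3L], Rs[3L], Rf[3L])
    ra_rem <- c(As[1L], Af[1L], As[1L], Af[1L])
    ra_tra <- c(As[2L], Af[2L], As[2L], Af[2L])
    ra_dth <- c(As[3L], Af[3L], As[3L], Af[3L])
    for (k in seq_along(M)) {
      m <- M[[k]]
      new <- matrix(0, 2L, 4L)
      new[1L, ] <- m[1L, ] * rh_rem + m[2L, ] * ra_tra
      new[2L, ] <- m[1L, ] * rh_tra + m[2L, ] * ra_rem
      dead <- dead + sum(m[1L, ] * rh_dth) + sum(m[2L, ] * ra_dth)
      M[[k]] <- new
    }
  }

  disc <- discount_factor(seq_len(n_cyc) - 1L, rate)
  w <- rep(1, n_cyc)
  term_cost <- term_qaly <- 0
  if (half_cycle) {
    w[1L] <- 0.5
    rw_end <- cycle_rewards(n_cyc)  # terminal occupancy, subsequent-year costs
    d_end <- discount_factor(n_cyc, rate)
    term_cost <- 0.5 * d_end * rw_end[1L]
    term_qaly <- 0.5 * d_end * rw_end[2L]
  }

  disc_cost_inc <- disc * (w * cost_inc + onetime_inc)
  disc_qaly_inc <- disc * w * qaly_inc

  out <- list(
    strategy = strategy$arm,
    total_discounted_cost = sum(disc_cost_inc) + term_cost,
    total_discounted_qaly = sum(disc_qaly_inc) + term_qaly,
    total_cost = sum(cost_inc + onetime_inc),
    total_qaly = sum(qaly_inc),
    horizon = n_cyc, start_age = start_age,
    discount_rate = rate, half_cycle = half_cycle
  )
  if (trace) {
    states <- do.call(rbind, trace_rows)
    increments <- data.frame(
      cycle = seq_len(n_cyc) - 1L,
      cost_inc = cost_inc + onetime_inc,
      qaly_inc = qaly_inc,
      disc_cost_inc = disc_cost_inc,
      disc_qaly_inc = disc_qaly_inc)
    out$trace <- list(states = states, increments = increments)
  }
  class(out) <- "ce_outcome"
  out
}

#' Run both strategy arms on the same parameter set
#'
#' @inheritParams run_cohort
#' @param ... Passed to \code{\link{run_cohort}}.
#' @return Named list with elements \code{TEST} and \code{NO_TEST}.
#' @export
run_strategies <- function(P, ...) {
  list(TEST = run_cohort(strategy_spec("TEST"), P, ...),
       NO_TEST = run_cohort(strategy_spec("NO_TEST"), P, ...))
}

#' @export
print.ce_outcome <- function(x, ...) {
  cat(sprintf("<ce_outcome> %s: %.2f USD, %.4f QALY (discounted, %d y)\n",
              x$strategy, x$total_discounted_cost, x$total_discounted_qaly,
              x$horizon))
  invisible(x)
}

#' Export a cohort trace as tidy CSV
#'
#' One row per (cycle, extended state) with occupancy, joined with the
#' cycle-level undiscounted and discounted cost and QALY increments.
#'
#' @param outcome A \code{ce_outcome} produced with \code{trace = TRUE}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
export_trace <- function(outcome, path) {
  if (is.null(outcome$trace)) stop("outcome has no trace; rerun with trace = TRUE")
  df <- merge(outcome$trace$states, outcome$trace$increments, by = "cycle")
  df <- df[order(df$cycle), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
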