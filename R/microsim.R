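# Synthetic cohort generator and individual-level microsimulation. Each
# individual owns a seed derived from (master seed, id), so enlarging the
# cohort never reshuffles existing individuals, and the two strategy arms
# simulated with the same master seed share random numbers (common random
# numbers, which tightens incremental contrasts).

# Deterministic 31-bit stream seed from (master, id, slot). Uses only exact
# double arithmetic below 2^53.
.derive_seed <- function(master, id, slot = 1L) {
  m <- 2147483647
  h <- (as.numeric(master) %% m)
  h <- (h * 48271 + as.numeric(id) * 9349 + as.numeric(slot) * 6007) %% m
  h <- (h * 16807 + 12345) %% m
  as.integer(h)
}

#' Generate a synthetic cohort of newly diagnosed PLHIV
#'
#' Emulates the modeled entry population: ages drawn uniformly on the
#' published diagnosis-age range (27-45, mean 36 by symmetry), diagnosis
#' stage Bernoulli (17.7\% AIDS), and transmitted resistance class drawn
#' from the transmitted-prevalence vector (NRTI 3\%, PI 0.1\%, INSTI 0.1\%,
#' otherwise none). Each individual's attributes come from their own derived
#' stream, so the first \code{k} individuals of a size-\code{n} cohort equal
#' the size-\code{k} cohort at the same seed.
#'
#' @param n Cohort size (>= 1).
#' @param seed Master seed (integer).
#' @param P A \code{drt_parameters} object.
#' @return A data frame (class \code{drt_cohort}) with columns \code{id},
#'   \code{age_at_dx}, \code{stage_at_dx}, \code{resistance},
#'   \code{sim_seed}; the master seed is kept in the \code{seed} attribute.
#' @export
generate_cohort <- function(n, seed, P = baseline_parameters()) {
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  age <- numeric(n); stage <- character(n); res <- character(n)
  lo <- P$cohort$age_range[1]; hi <- P$cohort$age_range[2]
  c_nrti <- P$tdr_nrti
  c_pi <- c_nrti + P$tdr_pi
  c_insti <- c_pi + P$tdr_insti
  old <- .save_rng()
  on.exit(.restore_rng(old))
  for (i in seq_len(n)) {
    set.seed(.derive_seed(seed, i, 1L))
    u <- runif(3)
    age[i] <- lo + (hi - lo) * u[1]
    stage[i] <- if (u[2] < P$p_aids_at_dx) "AIDS" else "HIV"
    res[i] <- if (u[3] < c_nrti) "NRTI"
      else if (u[3] < c_pi) "PI"
      else if (u[3] < c_insti) "INSTI"
      else "none"
  }
  out <- data.frame(
    id = seq_len(n), age_at_dx = age, stage_at_dx = stage, resistance = res,
    sim_seed = vapply(seq_len(n), function(i) .derive_seed(seed, i, 2L),
                      integer(1)))
  attr(out, "seed") <- seed
  class(out) <- c("drt_cohort", "data.frame")
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Precompute the lookup tables the inner loops need: `rows` holds the
# cumulative (remain, remain+transition) bounds for microsimulation draws,
# `raw` the (remain, transition, death) probabilities for the cohort engine.
.sim_tables <- function(P) {
  tt <- P$transition_table
  rows <- array(0, dim = c(4L, 4L, 2L),
                dimnames = list(.contexts, .age_bands, NULL))
  raw <- array(0, dim = c(4L, 4L, 3L),
               dimnames = list(.contexts, .age_bands,
                               c("remain", "transition", "death")))
  for (i in seq_len(nrow(tt))) {
    rows[tt$context[i], tt$age_band[i], 1L] <- tt$p_remain[i]
    rows[tt$context[i], tt$age_band[i], 2L] <-
      tt$p_remain[i] + tt$p_transition[i]
    raw[tt$context[i], tt$age_band[i], ] <-
      c(tt$p_remain[i], tt$p_transition[i], tt$p_death[i])
  }
  costs <- rbind(
    "DTG.HIV"  = c(P$cost_dtg_hiv_first, P$cost_dtg_hiv_subseq),
    "DTG.AIDS" = c(P$cost_dtg_aids_first, P$cost_dtg_aids_subseq),
    "PI.HIV"   = c(P$cost_pi_hiv_first, P$cost_pi_hiv_subseq),
    "PI.AIDS"  = c(P$cost_pi_aids_first, P$cost_pi_aids_subseq))
  list(rows = rows, raw = raw, costs = costs)
}

.band_index <- function(age) {
  if (age < 45) 1L else if (age < 55) 2L else if (age < 65) 3L else 4L
}

#' Simulate one individual trajectory
#'
#' Applies the arm's decision logic with the individual's own random stream:
#' entry regimen (with the test charged in the TEST arm), first-cycle
#' adverse-event switch, a suppression draw at each regimen initiation, a
#' failure-triggered test-and-switch to the PI line one cycle after failure
#' (acquired resistance class drawn at the switch), annual OI draws in the
#' AIDS stage, and age-banded stage/death transitions. Rewards are
#' discounted exactly as in the cohort engine.
#'
#' @param ind One row of a \code{\link{generate_cohort}} data frame (or a
#'   list with \code{age_at_dx}, \code{stage_at_dx}, \code{resistance},
#'   \code{sim_seed}).
#' @param strategy A \code{\link{strategy_spec}} or arm name.
#' @param P A \code{drt_parameters} object.
#' @param horizon Number of annual cycles.
#' @param record_events Keep the per-cycle event log (needed for
#'   \code{\link{replay_trajectory}}); off by default for speed.
#' @return A \code{drt_trajectory}: list with \code{disc_cost},
#'   \code{disc_qaly}, undiscounted totals, cycles survived, and optionally
#'   \code{events} (one row per lived cycle).
#' @export
simulate_individual <- function(ind, strategy, P, horizon = P$horizon_years,
                                record_events = FALSE) {
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  tabs <- .sim_tables(P)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  .simulate_one(ind, strategy, P, as.integer(horizon), tabs, record_events)
}

# Inner loop shared by simulate_individual and simulate_cohort. `tabs` from
# .sim_tables. RNG: a pre-drawn uniform vector consumed sequentially.
.simulate_one <- function(ind, strategy, P, horizon, tabs, record_events) {
  set.seed(ind$sim_seed)
  u <- runif(3L * horizon + 8L)
  ptr <- 0L
  nxt <- function(n = 1L) { ptr <<- ptr + 1L; u[ptr] }

  arm_test <- strategy$arm == "TEST"
  stage <- ind$stage_at_dx          # "HIV" | "AIDS"
  res <- ind$resistance
  a <- assign_initial_regimen(res, strategy, P)
  onetime0 <- a$one_time_cost
  if (a$regimen == "DTG" && nxt() < P$adverse_event_prob)
    a <- apply_adverse_event(a, res, strategy, P)
  regimen <- a$regimen
  suppressed <- nxt() < a$effectiveness
  line <- 1L

  dr <- P$discount_rate
  disc_cost <- disc_qaly <- cost_tot <- qaly_tot <- 0
  events <- if (record_events) vector("list", horizon) else NULL
  alive <- TRUE
  t <- 0L
  while (alive && t < horizon) {
    onetime <- if (t == 0L) onetime0 else 0
    if (t > 0L && line == 1L && !suppressed) {
      sw <- handle_failure(list(regimen = regimen), strategy, P, rng = nxt)
      onetime <- onetime + sw$one_time_cost
      regimen <- sw$regimen
      suppressed <- nxt() < sw$effectiveness
      line <- 2L
    }
    oi <- FALSE
    if (stage == "AIDS")
      oi <- nxt() < (if (suppressed) P$oi_prob_success else P$oi_prob_failure)

    cost <- tabs$costs[[paste0(regimen, ".", stage),
                        if (t == 0L) 1L else 2L]] + onetime
    utility <- if (stage == "HIV") P$util_hiv
      else if (oi) P$util_aids_oi else P$util_aids_no_oi
    d <- (1 + dr)^(-t)
    cost_tot <- cost_tot + cost
    qaly_tot <- qaly_tot + utility
    disc_cost <- disc_cost + d * cost
    disc_qaly <- disc_qaly + d * utility

    if (record_events)
      events[[t + 1L]] <- data.frame(
        cycle = t, stage = stage, oi = oi, regimen = regimen,
        suppressed = suppressed, line = line, onetime_cost = onetime)

    ctx <- if (stage == "HIV") {
      if (suppressed) 1L else 2L
    } else {
      if (oi) 4L else 3L
    }
    band <- .band_index(ind$age_at_dx + t)
    uu <- nxt()
    if (uu < tabs$rows[ctx, band, 1L]) {
      # remain
    } else if (uu < tabs$rows[ctx, band, 2L]) {
      stage <- if (stage == "HIV") "AIDS" else "HIV"
    } else {
      alive <- FALSE
    }
    t <- t + 1L
  }

  out <- list(id = ind$id %||% NA_integer_, arm = strategy$arm,
              disc_cost = disc_cost, disc_qaly = disc_qaly,
              cost = cost_tot, qaly = qaly_tot,
              cycles_lived = t, died = !alive)
  if (record_events) out$events <- do.call(rbind, events[seq_len(t)])
  class(out) <- "drt_trajectory"
  out
}

#' Recompute a trajectory's totals from its event log
#'
#' Replays the per-cycle event rows (stage, OI flag, regimen, one-time
#' costs) through the reward and discounting rules; the result must equal
#' the totals accumulated during simulation bit-for-bit.
#'
#' @param traj A \code{drt_trajectory} simulated with
#'   \code{record_events = TRUE}.
#' @param P The parameter set used to simulate it.
#' @return Named numeric: \code{disc_cost}, \code{disc_qaly}.
#' @export
replay_trajectory <- function(traj, P) {
  ev <- traj$events
  if (is.null(ev)) stop("trajectory has no event log")
  disc_cost <- disc_qaly <- 0
  for (i in seq_len(nrow(ev))) {
    st <- list(stage = ev$stage[i], oi = ev$oi[i], regimen = ev$regimen[i],
               years_since_entry = ev$cycle[i])
    rw <- cycle_reward(st, P)
    d <- discount_factor(ev$cycle[i], P$discount_rate)
    disc_cost <- disc_cost + d * (rw[["cost"]] + ev$onetime_cost[i])
    disc_qaly <- disc_qaly + d * rw[["utility"]]
  }
  c(disc_cost = disc_cost, disc_qaly = disc_qaly)
}

#' Simulate a whole cohort under one strategy
#'
#' @param cohort A \code{\link{generate_cohort}} data frame.
#' @param strategy A \code{\link{strategy_spec}} or arm name.
#' @param P A \code{drt_parameters} object.
#' @param horizon Number of annual cycles.
#' @return A \code{microsim_result}: data frame of per-individual discounted
#'   totals with the cohort seed and arm in attributes.
#' @export
simulate_cohort <- function(cohort, strategy, P, horizon = P$horizon_years) {
  if (is.character(strategy)) strategy <- strategy_spec(strategy)
  tabs <- .sim_tables(P)
  horizon <- as.integer(horizon)
  n <- nrow(cohort)
  dc <- dq <- numeric(n)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  for (i in seq_len(n)) {
    tr <- .simulate_one(list(id = cohort$id[i],
                             age_at_dx = cohort$age_at_dx[i],
                             stage_at_dx = cohort$stage_at_dx[i],
                             resistance = cohort$resistance[i],
                             sim_seed = cohort$sim_seed[i]),
                        strategy, P, horizon, tabs, FALSE)
    dc[i] <- tr$disc_cost
    dq[i] <- tr$disc_qaly
  }
  out <- data.frame(id = cohort$id, disc_cost = dc, disc_qaly = dq)
  attr(out, "arm") <- strategy$arm
  attr(out, "seed") <- attr(cohort, "seed")
  class(out) <- c("microsim_result", "data.frame")
  out
}

#' Aggregate microsimulation results
#'
#' Means and Monte-Carlo standard errors of discounted cost and QALY. With a
#' single trajectory (or identical replicates) the SE is 0.
#'
#' @param x A \code{microsim_result} data frame, or a list of
#'   \code{drt_trajectory} objects.
#' @return A list (class \code{ce_summary}): \code{mean_cost},
#'   \code{mean_qaly}, \code{se_cost}, \code{se_qaly}, \code{n}, and
#'   \code{total_discounted_cost}/\code{total_discounted_qaly} aliases so the
#'   summary can be fed to \code{\link{icer}}.
#' @export
aggregate_trajectories <- function(x) {
  if (inherits(x, "microsim_result")) {
    dc <- x$disc_cost; dq <- x$disc_qaly
  } else if (is.list(x) && length(x) &&
             all(vapply(x, inherits, logical(1), "drt_trajectory"))) {
    dc <- vapply(x, `[[`, numeric(1), "disc_cost")
    dq <- vapply(x, `[[`, numeric(1), "disc_qaly")
  } else stop("x must be a microsim_result or a non-empty list of trajectories")
  if (!length(dc)) stop("no trajectories to aggregate")
  n <- length(dc)
  se <- function(v) if (n < 2L) 0 else stats::sd(v) / sqrt(n)
  out <- list(mean_cost = mean(dc), mean_qaly = mean(dq),
              se_cost = se(dc), se_qaly = se(dq), n = n,
              total_discounted_cost = mean(dc),
              total_discounted_qaly = mean(dq))
  class(out) <- "ce_summary"
  out
}

#' @export
print.ce_summary <- function(x, ...) {
  cat(sprintf(
    "<ce_summary> n=%d: cost %.2f (SE %.2f), QALY %.4f (SE %.4f)\n",
    x$n, x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}
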