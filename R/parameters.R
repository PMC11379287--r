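#' @importFrom stats rbeta rgamma runif var sd
#' @importFrom utils write.csv
NULL

# Canonical level sets used throughout the package.
.stages <- c("HIV", "AIDS", "DEATH")
.resistance_classes <- c("none", "NRTI", "PI", "INSTI")
.regimens <- c("DTG", "PI")
.arms <- c("TEST", "NO_TEST")
.contexts <- c("hiv_suppressed", "hiv_failed", "aids_no_oi", "aids_oi")
.age_bands <- c("35-44", "45-54", "55-64", "65+")

# Names of scalar parameters that must lie in [0, 1].
.prob_params <- c(
  "tdr_nrti", "tdr_pi", "tdr_insti",
  "adr_nrti", "adr_pi", "adr_insti",
  "eff_dtg_none", "eff_dtg_nrti", "eff_dtg_pi", "eff_dtg_insti",
  "eff_pi_none", "eff_pi_nrti", "eff_pi_pi", "eff_pi_insti",
  "eff_dtg_tested", "eff_pi_tested",
  "adverse_event_prob", "oi_prob_failure", "oi_prob_success",
  "aids_to_hiv_prob", "p_hiv_to_aids_suppressed", "p_hiv_to_aids_failed",
  "p_aids_at_dx", "p_hiv_at_dx"
)

.cost_params <- c(
  "cost_dtg_hiv_first", "cost_dtg_hiv_subseq",
  "cost_dtg_aids_first", "cost_dtg_aids_subseq",
  "cost_pi_hiv_first", "cost_pi_hiv_subseq",
  "cost_pi_aids_first", "cost_pi_aids_subseq",
  "cost_drt"
)

.util_params <- c("util_hiv", "util_aids_no_oi", "util_aids_oi", "util_death")

#' Baseline parameter set
#'
#' Returns the full baseline parameter registry of the decision model: annual
#' regimen costs by stage and year since diagnosis, the Sanger resistance-test
#' cost, stage utilities, transmitted and acquired resistance prevalences,
#' annual viral-suppression probabilities by regimen and resistance context,
#' the age-banded transition table, opportunistic-infection (OI) incidence by
#' suppression status, discounting and horizon settings, cohort demographics,
#' and the uncertainty ranges used by the sensitivity analyses.
#'
#' Notable conventions baked into the baseline:
#' \itemize{
#'   \item Transmitted PI and INSTI resistance prevalences are recorded as
#'     0.1\% (a documented floor substituted for a literature point estimate
#'     of zero, so that the tested strategy can ever detect them).
#'   \item The transition table stores its published rows verbatim; the rows
#'     are row-stochastic as printed. The alternative 1.56x progression
#'     multiplier for failing patients is kept as a separate, documented
#'     parameter (\code{failure_progression_multiplier}) and is not applied
#'     to the table by default (see \code{\link{text_derived_fixture}}).
#'   \item The AIDS-with-OI death column already embodies the roughly
#'     two-fold OI mortality increase; \code{oi_death_multiplier} (2.1) is
#'     applied only when a user supplies custom AIDS rows without OI rows.
#'   \item Costs have no published uncertainty ranges; their default Gamma
#'     standard deviation is 20\% of the mean (\code{cost_sd_frac}).
#'   \item Probabilities and utilities without a published range default to
#'     +/-20\% of the point value (clipped to [0, 1]), read as a 95\%
#'     interval.
#' }
#'
#' @return An object of class \code{drt_parameters}: a named list with scalar
#'   entries, a \code{transition_table} data frame (16 rows: 4 clinical
#'   contexts x 4 age bands), a \code{cohort} list, and an \code{uncertainty}
#'   data frame (\code{parameter, low, high, family}).
#' @examples
#' P <- baseline_parameters()
#' P$cost_drt            # 1181.14
#' P$util_aids_oi        # 0.58
#' validate_parameters(P)
#' @export
baseline_parameters <- function() {
  tt <- data.frame(
    context = rep(.contexts, each = 4L),
    age_band = rep(.age_bands, times = 4L),
    p_remain = c(
      0.946, 0.933, 0.937, 0.93,   # HIV stage, suppressed
      0.944, 0.924, 0.93, 0.92,    # HIV stage, treatment failure
      0.86, 0.85, 0.82, 0.77,      # AIDS stage, no OI
      0.79, 0.77, 0.71, 0.61       # AIDS stage, with OI
    ),
    p_transition = c(
      rep(0.05, 8L),               # HIV -> AIDS progression
      rep(0.07, 8L)                # AIDS -> HIV re-suppression
    ),
    p_death = c(
      0.004, 0.017, 0.013, 0.02,
      0.006, 0.026, 0.02, 0.03,
      0.07, 0.08, 0.11, 0.16,
      0.14, 0.16, 0.22, 0.32
    ),
    stringsAsFactors = FALSE
  )

  P <- list(
    schema = 1L,

    # Annual care costs (USD), bottom-up totals taken as given.
    cost_dtg_hiv_first   = 5486.33,
    cost_dtg_hiv_subseq  = 5018.49,
    cost_dtg_aids_first  = 10972.66,
    cost_dtg_aids_subseq = 10036.98,
    cost_pi_hiv_first    = 5783.08,
    cost_pi_hiv_subseq   = 5195.05,
    cost_pi_aids_first   = 11566.17,
    cost_pi_aids_subseq  = 10390.10,
    cost_drt             = 1181.14,

    # Stage utilities (QALY weight per year).
    util_hiv         = 0.76,
    util_aids_no_oi  = 0.67,
    util_aids_oi     = 0.58,
    util_death       = 0,

    # Transmitted (at-diagnosis) resistance prevalence; PI/INSTI floored at 0.1%.
    tdr_nrti  = 0.03,
    tdr_pi    = 0.001,
    tdr_insti = 0.001,

    # Acquired (on-treatment) resistance prevalence, drawn at failure.
    adr_nrti  = 0.34,
    adr_pi    = 0.09,
    adr_insti = 0.01,

    # Annual probability of viral suppression by regimen x resistance context.
    eff_dtg_none   = 0.93,
    eff_dtg_nrti   = 0.82,
    eff_dtg_pi     = 0.93,
    eff_dtg_insti  = 0.35,
    eff_pi_none    = 0.83,
    eff_pi_nrti    = 0.72,
    eff_pi_pi      = 0.35,
    eff_pi_insti   = 0.83,
    eff_dtg_tested = 0.93,  # regimen tailored with resistance knowledge
    eff_pi_tested  = 0.83,

    adverse_event_prob = 0.05,  # one-shot DTG side-effect switch, first cycle
    oi_prob_failure    = 0.53,
    oi_prob_success    = 0.13,

    transition_table = tt,
    p_hiv_to_aids_suppressed = 0.05,
    p_hiv_to_aids_failed     = 0.05,
    aids_to_hiv_prob         = 0.07,
    failure_progression_multiplier = 1.56,
    oi_death_multiplier            = 2.1,

    discount_rate = 0.03,
    horizon_years = 40L,
    cycle_length  = 1,

    cohort = list(
      n = 1000L, mean_age = 36, age_range = c(27, 45),
      p_aids_at_dx = 0.177, p_hiv_at_dx = 0.823
    ),
    p_aids_at_dx = 0.177,
    p_hiv_at_dx  = 0.823,

    gdp_per_capita = 2746.4,
    wtp_multiplier = 3,

    cost_sd_frac = 0.2,  # Gamma SD as a fraction of the mean, for costs
    currency = list(unit = "USD", rial_per_usd = 42000)
  )

  P$uncertainty <- .baseline_uncertainty(P)
  class(P) <- "drt_parameters"
  P
}

# Uncertainty registry: published ranges where they exist, +/-20% defaults
# (clipped to [0,1]) for probabilities/utilities without one, Gamma with
# SD = cost_sd_frac * mean for costs (low/high recorded as mean -/+ 1.96 SD).
.baseline_uncertainty <- function(P) {
  pub <- list(
    eff_dtg_none   = c(0.90, 0.95),
    eff_dtg_nrti   = c(0.70, 0.90),
    eff_dtg_pi     = c(0.90, 0.95),
    eff_pi_none    = c(0.78, 0.85),
    eff_pi_nrti    = c(0.63, 0.79),
    eff_pi_insti   = c(0.78, 0.85),
    eff_dtg_tested = c(0.90, 0.95),
    eff_pi_tested  = c(0.78, 0.85),
    adr_nrti       = c(0.19, 0.50),
    adr_pi         = c(0.03, 0.18),
    adr_insti      = c(0.00, 0.04),
    tdr_nrti       = c(0.01, 0.06),
    tdr_pi         = c(0.00, 0.01),
    tdr_insti      = c(0.00, 0.08)
  )
  default20 <- c(
    "util_hiv", "util_aids_no_oi", "util_aids_oi",
    "oi_prob_failure", "oi_prob_success", "adverse_event_prob",
    "aids_to_hiv_prob", "p_hiv_to_aids_suppressed", "p_hiv_to_aids_failed",
    "p_aids_at_dx"
  )
  rows <- list()
  for (nm in names(pub)) {
    rows[[nm]] <- data.frame(parameter = nm, low = pub[[nm]][1],
                             high = pub[[nm]][2], family = "beta")
  }
  for (nm in default20) {
    pt <- P[[nm]]
    rows[[nm]] <- data.frame(parameter = nm,
                             low = max(0, 0.8 * pt),
                             high = min(1, 1.2 * pt),
                             family = "beta")
  }
  for (nm in .cost_params) {
    m <- P[[nm]]; s <- P$cost_sd_frac * m
    rows[[nm]] <- data.frame(parameter = nm,
                             low = max(0, m - 1.96 * s),
                             high = m + 1.96 * s,
                             family = "gamma")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Alternative fixture applying the text-derived failure progression multiplier
#'
#' The published transition table prints the same HIV-to-AIDS progression
#' probability (0.05) for suppressed and failing patients, while the
#' accompanying text states that treatment failure increases progression
#' 1.56-fold. The default baseline stores the table verbatim; this variant
#' rescales the failed-context progression to
#' \code{1.56 * p_hiv_to_aids_suppressed}, removing the excess from
#' \code{p_remain} so rows stay stochastic.
#'
#' @return A \code{drt_parameters} object.
#' @export
text_derived_fixture <- function() {
  P <- baseline_parameters()
  p <- P$failure_progression_multiplier * P$p_hiv_to_aids_suppressed
  P <- apply_overrides(P, list(p_hiv_to_aids_failed = p))
  P
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the registry and returns the
#' violations as data, not errors: probabilities and utilities in [0, 1],
#' non-negative costs, zero death utility, diagnosis-stage mix summing to 1,
#' each transition-table row summing to 1 within 1e-9, and each uncertainty
#' range bracketing its point value.
#'
#' @param P A \code{drt_parameters} object.
#' @return A data frame with columns \code{parameter} and \code{message}; zero
#'   rows means the set is valid.
#' @export
validate_parameters <- function(P) {
  bad <- list()
  note <- function(parameter, message) {
    bad[[length(bad) + 1L]] <<- data.frame(parameter = parameter,
                                           message = message)
  }
  for (nm in .prob_params) {
    v <- P[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      note(nm, sprintf("probability must be in [0,1], got %s", format(v)))
  }
  for (nm in .cost_params) {
    v <- P[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      note(nm, sprintf("cost must be >= 0, got %s", format(v)))
  }
  for (nm in .util_params) {
    v <- P[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      note(nm, sprintf("utility must be in [0,1], got %s", format(v)))
  }
  if (isTRUE(P$util_death != 0))
    note("util_death", "death utility must be 0")
  if (abs(P$p_aids_at_dx + P$p_hiv_at_dx - 1) > 1e-9)
    note("p_aids_at_dx", "diagnosis stage probabilities must sum to 1")

  tt <- P$transition_table
  if (!is.data.frame(tt) ||
      !all(c("context", "age_band", "p_remain", "p_transition", "p_death")
           %in% names(tt))) {
    note("transition_table", "missing or malformed transition table")
  } else {
    for (i in seq_len(nrow(tt))) {
      s <- tt$p_remain[i] + tt$p_transition[i] + tt$p_death[i]
      if (abs(s - 1) > 1e-9)
        note(sprintf("transition_table[%s,%s]", tt$context[i], tt$age_band[i]),
             sprintf("row sums to %.10f, expected 1", s))
      if (any(c(tt$p_remain[i], tt$p_transition[i], tt$p_death[i]) < 0) ||
          any(c(tt$p_remain[i], tt$p_transition[i], tt$p_death[i]) > 1))
        note(sprintf("transition_table[%s,%s]", tt$context[i], tt$age_band[i]),
             "entries must be in [0,1]")
    }
    missing_rows <- setdiff(
      paste(rep(.contexts, each = 4L), rep(.age_bands, 4L)),
      paste(tt$context, tt$age_band))
    if (length(missing_rows))
      note("transition_table",
           paste("missing rows:", paste(missing_rows, collapse = "; ")))
  }

  un <- P$uncertainty
  if (is.data.frame(un) && nrow(un)) {
    for (i in seq_len(nrow(un))) {
      nm <- un$parameter[i]
      pt <- P[[nm]]
      if (is.null(pt)) {
        note(nm, "uncertainty range for unknown parameter")
      } else if (!(un$low[i] <= pt + 1e-12 && pt <= un$high[i] + 1e-12)) {
        note(nm, sprintf("range [%g, %g] does not bracket point %g",
                         un$low[i], un$high[i], pt))
      }
    }
  }

  if (length(bad)) do.call(rbind, bad)
  else data.frame(parameter = character(), message = character())
}

#' Apply named overrides to a parameter set
#'
#' Sets scalar parameters by name and propagates the handful of scalars that
#' shadow transition-table columns: \code{p_hiv_to_aids_suppressed} and
#' \code{p_hiv_to_aids_failed} rewrite the progression column of their HIV
#' rows, \code{aids_to_hiv_prob} rewrites the re-suppression column of both
#' AIDS contexts, and \code{p_aids_at_dx} rebalances \code{p_hiv_at_dx}. In
#' every table rewrite \code{p_remain} absorbs the change so rows stay
#' stochastic; if \code{p_remain} would go negative, \code{p_transition} and
#' \code{p_death} are rescaled to sum to 1 and the row is flagged in the
#' returned object's \code{renormalized} attribute.
#'
#' @param P A \code{drt_parameters} object.
#' @param overrides Named list of replacement values.
#' @param validate Stop if the resulting set fails \code{validate_parameters}.
#' @return The modified \code{drt_parameters} object.
#' @export
apply_overrides <- function(P, overrides, validate = TRUE) {
  stopifnot(inherits(P, "drt_parameters"))
  if (length(overrides) == 0L) return(P)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
    stop("overrides must be a fully named list")
  n_renorm <- 0L

  set_tt <- function(context, col, value) {
    idx <- P$transition_table$context %in% context
    P$transition_table[[col]][idx] <<- value
    # rebalance p_remain
    for (i in which(idx)) {
      rem <- 1 - P$transition_table$p_transition[i] -
        P$transition_table$p_death[i]
      if (rem < 0) {
        tot <- P$transition_table$p_transition[i] +
          P$transition_table$p_death[i]
        P$transition_table$p_transition[i] <<-
          P$transition_table$p_transition[i] / tot
        P$transition_table$p_death[i] <<- P$transition_table$p_death[i] / tot
        rem <- 0
        n_renorm <<- n_renorm + 1L
      }
      P$transition_table$p_remain[i] <<- rem
    }
  }

  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    if (nm == "transition_table" || nm == "uncertainty" || nm == "cohort") {
      P[[nm]] <- val
      next
    }
    if (is.null(P[[nm]]))
      stop(sprintf("unknown parameter '%s'", nm))
    P[[nm]] <- val
    # keep the uncertainty range bracketing the (possibly moved) point
    if (is.numeric(val) && length(val) == 1L && is.data.frame(P$uncertainty)) {
      j <- which(P$uncertainty$parameter == nm)
      if (length(j) == 1L) {
        P$uncertainty$low[j] <- min(P$uncertainty$low[j], val)
        P$uncertainty$high[j] <- max(P$uncertainty$high[j], val)
      }
    }
    switch(nm,
      p_hiv_to_aids_suppressed = set_tt("hiv_suppressed", "p_transition", val),
      p_hiv_to_aids_failed     = set_tt("hiv_failed", "p_transition", val),
      aids_to_hiv_prob = set_tt(c("aids_no_oi", "aids_oi"),
                                "p_transition", val),
      p_aids_at_dx = {
        P$p_hiv_at_dx <- 1 - val
        P$cohort$p_aids_at_dx <- val
        P$cohort$p_hiv_at_dx <- 1 - val
      },
      p_hiv_at_dx = {
        P$p_aids_at_dx <- 1 - val
        P$cohort$p_hiv_at_dx <- val
        P$cohort$p_aids_at_dx <- 1 - val
      }
    )
  }
  attr(P, "renormalized") <- n_renorm
  if (validate) {
    rep <- validate_parameters(P)
    if (nrow(rep))
      stop("invalid parameter value(s): ",
           paste(sprintf("%s (%s)", rep$parameter, rep$message),
                 collapse = "; "))
  }
  P
}

#' Load a parameter configuration
#'
#' Reads a flat-namespaced JSON configuration (schema version 1) and overlays
#' it on the baseline fixture: any key absent from the file inherits its
#' baseline value. The merged set is validated; out-of-range values raise an
#' error naming the parameter.
#'
#' @param config Path to a JSON file, a JSON string, or a named list of
#'   overrides. \code{NULL} or an empty list returns the baseline unchanged.
#' @return A validated \code{drt_parameters} object.
#' @export
load_parameters <- function(config = NULL) {
  P <- baseline_parameters()
  if (is.null(config)) return(P)
  if (is.character(config)) {
    ov <- tryCatch(
      jsonlite::fromJSON(config, simplifyVector = TRUE),
      error = function(e) stop("failed to parse config: ",
                               conditionMessage(e), call. = FALSE))
  } else if (is.list(config)) {
    ov <- config
  } else stop("config must be a path, JSON string, or named list")
  ov$schema <- NULL
  if (!is.null(ov$transition_table))
    ov$transition_table <- as.data.frame(ov$transition_table)
  if (!is.null(ov$uncertainty))
    ov$uncertainty <- as.data.frame(ov$uncertainty)
  apply_overrides(P, ov, validate = TRUE)
}

#' Save a parameter set to JSON
#'
#' Writes the full registry (schema-versioned, full precision) so that
#' \code{load_parameters(save_parameters(P, f))} round-trips exactly.
#'
#' @param P A \code{drt_parameters} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
save_parameters <- function(P, path) {
  stopifnot(inherits(P, "drt_parameters"))
  x <- unclass(P)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.drt_parameters <- function(x, ...) {
  cat("<drt_parameters> schema", x$schema, "\n")
  cat(sprintf("  horizon %d y, discount %.1f%%, WTP %s x GDP (%.1f USD)\n",
              x$horizon_years, 100 * x$discount_rate, x$wtp_multiplier,
              x$gdp_per_capita))
  cat(sprintf("  cohort n=%d, mean age %.0f, AIDS at dx %.1f%%\n",
              x$cohort$n, x$cohort$mean_age, 100 * x$p_aids_at_dx))
  cat(sprintf("  %d transition rows, %d uncertain parameters\n",
              nrow(x$transition_table), nrow(x$uncertainty)))
  invisible(x)
}

# Internal: transition row lookup (named numeric remain/transition/death).
.tt_row <- function(P, context, age) {
  band <- age_band(age)
  tt <- P$transition_table
  i <- which(tt$context == context & tt$age_band == band)
  if (length(i) != 1L)
    stop(sprintf("no transition row for context '%s', age band '%s'",
                 context, band))
  c(remain = tt$p_remain[i], transition = tt$p_transition[i],
    death = tt$p_death[i])
}

#' Age band used by the transition table
#'
#' Ages below 35 use the youngest (35-44) band, since diagnosis ages start at
#' 27 and the table has no younger stratum; ages 65 and over use the open
#' top band.
#'
#' @param age Age in years (vectorized).
#' @return Character vector of band labels.
#' @export
age_band <- function(age) {
  stopifnot(all(age >= 0))
  ifelse(age < 45, "35-44",
         ifelse(age < 55, "45-54",
                ifelse(age < 65, "55-64", "65+")))
}
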