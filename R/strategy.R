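# Decision logic of the two comparator arms: informed vs empiric first-line
# regimen assignment, the one-shot adverse-event switch, failure-triggered
# resistance testing with a switch to the protease-inhibitor line, OI
# incidence, and per-cycle cost/utility rewards.

#' Construct a strategy specification
#'
#' The model compares two arms. \code{TEST}: every newly diagnosed person
#' receives a genotypic drug-resistance test (DRT) and the first regimen is
#' chosen with knowledge of transmitted resistance. \code{NO_TEST}: everyone
#' starts empiric dolutegravir (DTG)-based therapy, and effectiveness is
#' governed by their true (unknown) resistance class. In both arms treatment
#' failure triggers a resistance test and a switch to the protease-inhibitor
#' (PI)-based second line.
#'
#' @param arm \code{"TEST"} or \code{"NO_TEST"}.
#' @return A \code{drt_strategy} object.
#' @export
strategy_spec <- function(arm = c("TEST", "NO_TEST")) {
  arm <- match.arg(arm)
  structure(list(arm = arm, switch_regimen = "PI", retest_on_failure = TRUE),
            class = "drt_strategy")
}

#' @export
print.drt_strategy <- function(x, ...) {
  cat("<drt_strategy>", x$arm,
      "| switch regimen:", x$switch_regimen,
      "| retest on failure:", x$retest_on_failure, "\n")
  invisible(x)
}

# Effectiveness lookup for a regimen given a (known) resistance class.
.eff_by_class <- function(regimen, class, P) {
  key <- paste0("eff_", tolower(regimen), "_",
                c(none = "none", NRTI = "nrti", PI = "pi",
                  INSTI = "insti")[[class]])
  P[[key]]
}

#' Assign the initial regimen at diagnosis
#'
#' In the \code{TEST} arm the test cost is charged once at entry and the
#' regimen is tailored: DTG with the "under resistance testing" suppression
#' probability unless transmitted INSTI resistance is found, in which case a
#' PI-based regimen is started. In the \code{NO_TEST} arm everyone starts
#' DTG and the suppression probability is determined by the true resistance
#' class.
#'
#' @param resistance One of \code{"none"}, \code{"NRTI"}, \code{"PI"},
#'   \code{"INSTI"} (the transmitted class).
#' @param strategy A \code{\link{strategy_spec}}.
#' @param P A \code{drt_parameters} object.
#' @return A regimen assignment: list with \code{regimen},
#'   \code{effectiveness}, \code{informed}, \code{one_time_cost}.
#' @export
assign_initial_regimen <- function(resistance, strategy, P) {
  if (!resistance %in% .resistance_classes)
    stop(sprintf("unknown resistance class '%s'", resistance))
  stopifnot(inherits(strategy, "drt_strategy"))
  if (strategy$arm == "TEST") {
    if (resistance == "INSTI") {
      list(regimen = "PI", effectiveness = P$eff_pi_tested,
           informed = TRUE, one_time_cost = P$cost_drt)
    } else {
      list(regimen = "DTG", effectiveness = P$eff_dtg_tested,
           informed = TRUE, one_time_cost = P$cost_drt)
    }
  } else {
    list(regimen = "DTG",
         effectiveness = .eff_by_class("DTG", resistance, P),
         informed = FALSE, one_time_cost = 0)
  }
}

#' Switch regimen after a dolutegravir adverse event
#'
#' A one-shot 5\% probability of DTG intolerance in the first cycle forces a
#' switch to the PI-based regimen. In the \code{TEST} arm the switch is made
#' with resistance knowledge (tested PI effectiveness); in \code{NO_TEST} the
#' PI effectiveness is governed by the true resistance class.
#'
#' @inheritParams assign_initial_regimen
#' @param current The current regimen assignment (must be DTG-based).
#' @return The post-switch regimen assignment (no test cost: the switch is
#'   driven by toxicity, not failure).
#' @export
apply_adverse_event <- function(current, resistance, strategy, P) {
  if (!identical(current$regimen, "DTG"))
    stop("adverse-event switch applies only to a DTG-based regimen")
  if (strategy$arm == "TEST") {
    list(regimen = "PI", effectiveness = P$eff_pi_tested,
         informed = TRUE, one_time_cost = 0)
  } else {
    list(regimen = "PI",
         effectiveness = .eff_by_class("PI", resistance, P),
         informed = FALSE, one_time_cost = 0)
  }
}

# Expected second-line PI effectiveness, marginalized over the acquired
# resistance classes drawn at failure (used by the cohort engine).
post_failure_effectiveness <- function(P) {
  p_none <- 1 - P$adr_nrti - P$adr_pi - P$adr_insti
  P$adr_nrti * P$eff_pi_nrti + P$adr_pi * P$eff_pi_pi +
    P$adr_insti * P$eff_pi_insti + p_none * P$eff_pi_none
}

#' Handle treatment failure: test, draw acquired resistance, switch to PI
#'
#' In both arms a failing patient is retested (one test cost charged at the
#' failure-triggered switch), an acquired resistance class is drawn from the
#' acquired-prevalence vector, and the regimen switches to the PI-based line
#' with the informed effectiveness for the drawn class. With \code{rng =
#' NULL} (cohort mode) no class is drawn and the returned effectiveness is
#' the expectation over classes. A failure of the second line is persistent:
#' no further switches are modeled.
#'
#' @param current The failing regimen assignment.
#' @param strategy A \code{\link{strategy_spec}}.
#' @param P A \code{drt_parameters} object.
#' @param rng \code{NULL} for the cohort expectation, or a function
#'   \code{rng(1)} returning one uniform deviate (microsimulation).
#' @return The second-line assignment, with \code{drawn_class} (\code{NA} in
#'   cohort mode) and \code{one_time_cost} equal to the test cost.
#' @export
handle_failure <- function(current, strategy, P, rng = NULL) {
  stopifnot(inherits(strategy, "drt_strategy"))
  if (is.null(rng)) {
    list(regimen = "PI", effectiveness = post_failure_effectiveness(P),
         informed = TRUE, one_time_cost = P$cost_drt, drawn_class = NA)
  } else {
    u <- rng(1)
    cls <- if (u < P$adr_nrti) "NRTI"
      else if (u < P$adr_nrti + P$adr_pi) "PI"
      else if (u < P$adr_nrti + P$adr_pi + P$adr_insti) "INSTI"
      else "none"
    list(regimen = "PI", effectiveness = .eff_by_class("PI", cls, P),
         informed = TRUE, one_time_cost = P$cost_drt, drawn_class = cls)
  }
}

#' Annual opportunistic-infection probability by suppression status
#'
#' @param suppression \code{"suppressed"} or \code{"failed"}.
#' @param P A \code{drt_parameters} object.
#' @return Probability that an AIDS-stage person has an OI this cycle.
#' @export
oi_probability <- function(suppression, P) {
  switch(match.arg(suppression, c("suppressed", "failed")),
         suppressed = P$oi_prob_success,
         failed = P$oi_prob_failure)
}

# Annual care cost for a living person: regimen x stage x year-since-diagnosis.
.care_cost <- function(regimen, stage, first_year, P) {
  key <- paste0("cost_", tolower(regimen), "_", tolower(stage), "_",
                if (first_year) "first" else "subseq")
  P[[key]]
}

#' Per-cycle reward of an extended state
#'
#' Utility is 0.76 in the HIV stage, 0.67 in AIDS without OI, 0.58 in AIDS
#' with OI, and 0 when dead. Cost is the annual care cost of the current
#' regimen in the current stage, using the first-year cost row in the first
#' model cycle after diagnosis and the subsequent-year row afterwards; death
#' costs nothing. One-time test costs are event costs handled by the engines,
#' not by this function.
#'
#' @param state List with \code{stage} (\code{"HIV"}, \code{"AIDS"},
#'   \code{"DEATH"}), \code{oi} (logical, AIDS only), \code{regimen}, and
#'   \code{years_since_entry} (0 = first model year).
#' @param P A \code{drt_parameters} object.
#' @return Named numeric: \code{cost} (USD/year), \code{utility} (QALY/year).
#' @export
cycle_reward <- function(state, P) {
  stage <- match.arg(state$stage, .stages)
  if (stage == "DEATH") return(c(cost = 0, utility = 0))
  oi <- isTRUE(state$oi)
  utility <- if (stage == "HIV") P$util_hiv
    else if (oi) P$util_aids_oi else P$util_aids_no_oi
  cost <- .care_cost(state$regimen, stage,
                     first_year = (state$years_since_entry %||% 0L) == 0L, P)
  c(cost = cost, utility = utility)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
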