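# Incremental analysis: ICER, dominance classification, net monetary
# benefit, and the willingness-to-pay threshold rule.

#' Willingness-to-pay threshold
#'
#' The decision threshold is a multiple of GDP per capita per QALY; the
#' baseline uses three times the 2020 GDP per capita (3 x 2,746.4 = 8,239.2
#' USD/QALY).
#'
#' @param gdp_per_capita GDP per capita in USD (>= 0).
#' @param multiplier Threshold multiplier (default 3).
#' @return USD per QALY.
#' @export
wtp_threshold <- function(gdp_per_capita, multiplier = 3) {
  stopifnot(gdp_per_capita >= 0)
  gdp_per_capita * multiplier
}

#' Incremental cost-effectiveness ratio
#'
#' Computes \eqn{\Delta C / \Delta E} between an intervention and a
#' comparator. Degenerate quadrants become classifications instead of signed
#' infinities: an intervention that is cheaper and more effective is
#' \code{"dominant"}, costlier and less effective is \code{"dominated"}, and
#' identical outcomes are \code{"undefined"}. The cost-effectiveness flag is
#' true when the intervention is dominant, or when \eqn{\Delta E > 0} and
#' the ICER does not exceed the willingness-to-pay threshold.
#'
#' @param intervention,comparator \code{ce_outcome} or \code{ce_summary}
#'   objects (anything with \code{total_discounted_cost} and
#'   \code{total_discounted_qaly}), or plain lists with those fields.
#' @param wtp Willingness-to-pay threshold in USD/QALY.
#' @return An \code{icer_result}: \code{delta_cost}, \code{delta_effect},
#'   \code{icer} (numeric or \code{NA}), \code{classification}, \code{wtp},
#'   \code{cost_effective}.
#' @export
icer <- function(intervention, comparator, wtp = NULL) {
  dc <- intervention$total_discounted_cost - comparator$total_discounted_cost
  de <- intervention$total_discounted_qaly - comparator$total_discounted_qaly
  stopifnot(is.finite(dc), is.finite(de))
  classification <-
    if (dc == 0 && de == 0) "undefined"
    else if (de > 0 && dc <= 0) "dominant"
    else if (de < 0 && dc >= 0) "dominated"
    else if (de == 0) if (dc > 0) "dominated" else "dominant"
    else "ratio"
  ratio <- if (de != 0) dc / de else NA_real_
  ce <- if (is.null(wtp)) NA else {
    classification == "dominant" ||
      (de > 0 && !is.na(ratio) && ratio <= wtp)
  }
  structure(list(delta_cost = dc, delta_effect = de, icer = ratio,
                 classification = classification, wtp = wtp,
                 cost_effective = ce),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> dCost %.2f USD, dQALY %.6f", x$delta_cost,
              x$delta_effect))
  if (x$classification == "ratio")
    cat(sprintf(", ICER %.2f USD/QALY", x$icer))
  else cat(sprintf(" [%s]", x$classification))
  if (!is.null(x$wtp))
    cat(sprintf(" | WTP %.1f: %s", x$wtp,
                if (isTRUE(x$cost_effective)) "cost-effective"
                else "not cost-effective"))
  cat("\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' \code{wtp * QALY - cost}. The incremental NMB of two strategies is
#' positive exactly when the intervention is cost-effective at that
#' threshold (for \eqn{\Delta E > 0} it agrees with the ICER rule).
#'
#' @param outcome A \code{ce_outcome}/\code{ce_summary}, or a list with
#'   \code{total_discounted_cost} and \code{total_discounted_qaly}.
#' @param wtp Willingness-to-pay in USD/QALY (>= 0).
#' @return USD.
#' @export
nmb <- function(outcome, wtp) {
  stopifnot(wtp >= 0)
  wtp * outcome$total_discounted_qaly - outcome$total_discounted_cost
}

#' Build a plain cost-effectiveness outcome
#'
#' Convenience constructor for feeding externally supplied totals (for
#' example published strategy totals) into \code{\link{icer}} and
#' \code{\link{nmb}}.
#'
#' @param cost Total discounted cost (USD).
#' @param qaly Total discounted QALYs.
#' @param strategy Optional label.
#' @return A \code{ce_outcome}-like list.
#' @export
ce_outcome <- function(cost, qaly, strategy = NA_character_) {
  stopifnot(is.finite(cost), is.finite(qaly))
  structure(list(strategy = strategy, total_discounted_cost = cost,
                 total_discounted_qaly = qaly),
            class = "ce_outcome")
}
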