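# ICER, net monetary benefit and scenario analyses on the incremental
# cost-effectiveness plane.

#' Incremental cost-effectiveness ratio and plane quadrant
#'
#' The ICER is delta cost over delta QALY, defined only when the QALY
#' difference is non-zero. The quadrant follows the incremental
#' cost-effectiveness plane convention with effect on the horizontal axis:
#' NE = costlier and more effective, SE = cheaper and more effective
#' (dominant), NW = costlier and less effective (dominated), SW = cheaper and
#' less effective. A zero difference on either axis is reported as a
#' boundary, not assigned to a quadrant.
#'
#' @param delta_cost Incremental cost (money).
#' @param delta_qaly Incremental effect (QALY).
#' @param delta_ly Optional incremental life-years, carried through for
#'   reporting.
#' @return Object of class `cea_result` with fields `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer_per_qaly` (`NA` when undefined) and
#'   `quadrant`.
#' @export
compute_icer <- function(delta_cost, delta_qaly, delta_ly = NA_real_) {
  if (is.na(delta_cost) || is.na(delta_qaly) ||
      !is.finite(delta_cost) || !is.finite(delta_qaly)) {
    stop("delta_cost and delta_qaly must be finite numbers", call. = FALSE)
  }
  icer <- if (delta_qaly != 0) delta_cost / delta_qaly else NA_real_
  quadrant <- plane_quadrant(delta_cost, delta_qaly)
  structure(list(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 delta_ly = delta_ly, icer_per_qaly = icer,
                 quadrant = quadrant),
            class = "cea_result")
}

plane_quadrant <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) return("boundary: no difference")
  if (delta_qaly == 0) {
    return(if (delta_cost > 0) "boundary: costlier, no effect difference"
           else "boundary: cheaper, no effect difference")
  }
  if (delta_cost == 0) {
    return(if (delta_qaly > 0) "boundary: equal cost, more effective"
           else "boundary: equal cost, less effective")
  }
  if (delta_cost > 0 && delta_qaly > 0) return("NE: costlier and more effective")
  if (delta_cost < 0 && delta_qaly > 0) return("SE: cheaper and more effective (dominant)")
  if (delta_cost > 0 && delta_qaly < 0) return("NW: costlier and less effective (dominated)")
  "SW: cheaper and less effective"
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Incremental cost:  EUR %.0f\n", x$delta_cost))
  if (!is.na(x$delta_ly)) cat(sprintf("Incremental LY:    %.4f\n", x$delta_ly))
  cat(sprintf("Incremental QALY:  %.4f\n", x$delta_qaly))
  if (is.na(x$icer_per_qaly)) {
    cat("ICER:              undefined (no QALY difference)\n")
  } else {
    cat(sprintf("ICER:              EUR %.0f per QALY\n", x$icer_per_qaly))
  }
  cat(sprintf("Plane position:    %s\n", x$quadrant))
  invisible(x)
}

#' Net monetary benefit
#'
#' `threshold * delta_qaly - delta_cost`; for a positive QALY gain, a
#' positive net monetary benefit is equivalent to the ICER lying below the
#' willingness-to-pay threshold.
#'
#' @param delta_cost Incremental cost.
#' @param delta_qaly Incremental QALYs.
#' @param threshold Willingness-to-pay per QALY (default EUR 40,000).
#' @return Net monetary benefit (money).
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, threshold = 40000) {
  if (!is.finite(delta_cost) || !is.finite(delta_qaly) || !is.finite(threshold)) {
    stop("all inputs must be finite", call. = FALSE)
  }
  threshold * delta_qaly - delta_cost
}

#' Willingness-to-pay decision configuration
#'
#' @param wtp_threshold_per_qaly Maximum acceptable cost per QALY gained
#'   (default EUR 40,000, the threshold applied in the Dutch setting).
#' @return Object of class `decision_config`.
#' @export
decision_config <- function(wtp_threshold_per_qaly = 40000) {
  if (!is.finite(wtp_threshold_per_qaly) || wtp_threshold_per_qaly <= 0) {
    stop("wtp_threshold_per_qaly must be positive", call. = FALSE)
  }
  structure(list(wtp_threshold_per_qaly = wtp_threshold_per_qaly),
            class = "decision_config")
}

#' Base-case cost-utility result
#'
#' Convenience wrapper combining [incremental_effects()] and
#' [incremental_cost()] into a [compute_icer()] result.
#'
#' @param trial A [two_arm_trial()].
#' @param utilities A [health_state_utilities()].
#' @param costs A [cost_inputs()].
#' @return A `cea_result`.
#' @export
base_case <- function(trial = default_trial(),
                      utilities = health_state_utilities(),
                      costs = cost_inputs()) {
  eff <- incremental_effects(trial, utilities)
  cost <- incremental_cost(costs)
  compute_icer(cost$total_incremental_cost, eff$qalys, eff$life_years)
}

#' Zero-drug-price scenario
#'
#' Recomputes the incremental cost with the cetuximab price set to zero
#' (leaving EGFR screening and the additional day-treatment visits, with
#' their uplift) and divides by the unchanged incremental QALYs. Even a free
#' drug leaves a positive ICER because of these fixed incremental items.
#'
#' @param costs A [cost_inputs()].
#' @param trial A [two_arm_trial()].
#' @param utilities A [health_state_utilities()].
#' @return A `cea_result` for the scenario.
#' @export
zero_drug_scenario <- function(costs = cost_inputs(),
                               trial = default_trial(),
                               utilities = health_state_utilities()) {
  stopifnot(inherits(costs, "cost_inputs"))
  free <- costs
  free$cetuximab_price_per_100mg <- 0
  base_case(trial, utilities, free)
}
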