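# One-way (tornado) and probabilistic (Monte Carlo) sensitivity analyses.

TORNADO_PARAMETERS <- c(
  "control_mean_os", "control_mean_pfs",
  "intervention_mean_os", "intervention_mean_pfs",
  "u_pfs", "mean_cumulative_dose_mg", "cetuximab_price_per_100mg",
  "outpatient_visit_cost", "extra_visits_per_patient",
  "egfr_test_cost", "egfr_positive_fraction",
  "overhead_fraction", "housing_fraction")

# Rebuild the model with one named parameter replaced and return the ICER.
# Errors from violated invariants (e.g. a perturbed PFS exceeding OS) are
# converted to NA so the tornado can flag the row as infeasible.
evaluate_with_parameter <- function(name, value, trial, utilities, costs) {
  res <- tryCatch({
    tr <- trial
    u <- utilities
    ci <- costs
    if (name %in% c("control_mean_os", "control_mean_pfs",
                    "intervention_mean_os", "intervention_mean_pfs")) {
      arm <- if (startsWith(name, "control")) "control" else "intervention"
      field <- if (endsWith(name, "os")) "mean_os_months" else "mean_pfs_months"
      s <- tr[[arm]]
      s[[field]] <- value
      tr[[arm]] <- survival_summary(
        n = s$n, mean_os_months = s$mean_os_months,
        mean_pfs_months = s$mean_pfs_months,
        median_os_months = s$median_os_months,
        median_pfs_months = s$median_pfs_months,
        se_mean_os_months = s$se_mean_os_months,
        se_mean_pfs_months = s$se_mean_pfs_months)
    } else if (name == "u_pfs") {
      u <- health_state_utilities(u_pfs = value,
                                  u_asymptomatic_alt = u$u_asymptomatic_alt)
    } else {
      args <- unclass(ci)
      args[[name]] <- value
      ci <- do.call(cost_inputs, args)
    }
    base_case(tr, u, ci)$icer_per_qaly
  }, error = function(e) NA_real_)
  res
}

base_parameter_values <- function(trial, utilities, costs) {
  c(control_mean_os = trial$control$mean_os_months,
    control_mean_pfs = trial$control$mean_pfs_months,
    intervention_mean_os = trial$intervention$mean_os_months,
    intervention_mean_pfs = trial$intervention$mean_pfs_months,
    u_pfs = utilities$u_pfs,
    mean_cumulative_dose_mg = costs$mean_cumulative_dose_mg,
    cetuximab_price_per_100mg = costs$cetuximab_price_per_100mg,
    outpatient_visit_cost = costs$outpatient_visit_cost,
    extra_visits_per_patient = costs$extra_visits_per_patient,
    egfr_test_cost = costs$egfr_test_cost,
    egfr_positive_fraction = costs$egfr_positive_fraction,
    overhead_fraction = costs$overhead_fraction,
    housing_fraction = costs$housing_fraction)
}

#' One-way tornado sensitivity analysis
#'
#' Varies every model input one at a time by the given fraction in both
#' directions (default +/- 10%), holding all other inputs at their base
#' values, and records the resulting ICERs. Rows are sorted by descending
#' ICER range width (tornado order). A perturbation that violates a model
#' invariant (for example a mean PFS pushed above the mean OS) is flagged
#' infeasible rather than silently dropped; its ICER is `NA`.
#'
#' @param trial A [two_arm_trial()].
#' @param utilities A [health_state_utilities()].
#' @param costs A [cost_inputs()].
#' @param perturbation Relative perturbation (default 0.10).
#' @return A data frame of class `tornado_result` with columns
#'   `parameter`, `base_value`, `low_value`, `high_value`, `icer_at_low`,
#'   `icer_at_high`, `range_width`, `infeasible`.
#' @export
tornado <- function(trial = default_trial(),
                    utilities = health_state_utilities(),
                    costs = cost_inputs(),
                    perturbation = 0.10) {
  stopifnot(inherits(trial, "two_arm_trial"),
            inherits(utilities, "health_state_utilities"),
            inherits(costs, "cost_inputs"))
  if (!is.finite(perturbation) || perturbation <= 0 || perturbation >= 1) {
    stop("perturbation must lie in (0, 1)", call. = FALSE)
  }
  base <- base_case(trial, utilities, costs)
  if (is.na(base$icer_per_qaly)) {
    stop("base case has no defined ICER; tornado analysis is meaningless",
         call. = FALSE)
  }
  bases <- base_parameter_values(trial, utilities, costs)
  rows <- lapply(names(bases), function(p) {
    b <- bases[[p]]
    lo <- b * (1 - perturbation)
    hi <- b * (1 + perturbation)
    icer_lo <- evaluate_with_parameter(p, lo, trial, utilities, costs)
    icer_hi <- evaluate_with_parameter(p, hi, trial, utilities, costs)
    data.frame(parameter = p, base_value = b,
               low_value = lo, high_value = hi,
               icer_at_low = icer_lo, icer_at_high = icer_hi,
               range_width = abs(icer_hi - icer_lo),
               infeasible = is.na(icer_lo) || is.na(icer_hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range_width, out$parameter, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer_per_qaly
  attr(out, "perturbation") <- perturbation
  class(out) <- c("tornado_result", class(out))
  out
}

#' Configuration for the probabilistic sensitivity analysis
#'
#' Only the four arm-level survival means are sampled; every other model
#' parameter is held constant.
#'
#' @param n_iterations Number of simulated trials (default 1,000).
#' @param seed Integer seed.
#' @param threshold Willingness-to-pay threshold per QALY (default 40,000).
#' @return Object of class `psa_config`.
#' @export
psa_config <- function(n_iterations = 1000L, seed = 1L, threshold = 40000) {
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1) {
    stop("n_iterations must be a positive integer", call. = FALSE)
  }
  if (!is.finite(threshold) || threshold <= 0) {
    stop("threshold must be positive", call. = FALSE)
  }
  structure(list(n_iterations = n_iterations, seed = as.integer(seed),
                 threshold = threshold,
                 parameters_sampled = c("control_mean_os", "control_mean_pfs",
                                        "intervention_mean_os",
                                        "intervention_mean_pfs")),
            class = "psa_config")
}

#' Draw one PSA replicate of the trial
#'
#' Replaces each of the four arm-level survival means by a normal draw
#' centred at the base mean with standard deviation equal to the standard
#' error of that mean, reflecting sampling uncertainty of the trial means.
#' Draws in which an arm's mean PFS is non-positive or exceeds its mean OS
#' are rejected and redrawn. Uses the current RNG state; seed via
#' `set.seed()` or [run_psa()].
#'
#' @param trial A [two_arm_trial()] with all four standard errors populated.
#' @param max_rejections Safety cap on redraws per arm.
#' @return A perturbed `two_arm_trial`; the number of rejected draws is
#'   attached as attribute `"rejections"`.
#' @export
draw_psa_sample <- function(trial, max_rejections = 1000L) {
  stopifnot(inherits(trial, "two_arm_trial"))
  for (arm in c("control", "intervention")) {
    s <- trial[[arm]]
    if (is.na(s$se_mean_os_months) || is.na(s$se_mean_pfs_months)) {
      stop(sprintf("%s arm: standard errors are required to draw a PSA sample",
                   arm), call. = FALSE)
    }
  }
  rejections <- 0L
  draw_arm <- function(s) {
    repeat {
      os <- stats::rnorm(1, s$mean_os_months, s$se_mean_os_months)
      pfs <- stats::rnorm(1, s$mean_pfs_months, s$se_mean_pfs_months)
      if (pfs > 0 && pfs <= os) break
      rejections <<- rejections + 1L
      if (rejections > max_rejections) {
        stop("PSA rejection limit exceeded; check the standard errors",
             call. = FALSE)
      }
    }
    survival_summary(n = s$n, mean_os_months = os, mean_pfs_months = pfs,
                     se_mean_os_months = s$se_mean_os_months,
                     se_mean_pfs_months = s$se_mean_pfs_months)
  }
  out <- two_arm_trial(control = draw_arm(trial$control),
                       intervention = draw_arm(trial$intervention))
  attr(out, "rejections") <- rejections
  out
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Runs `n_iterations` simulated trials: each replicate redraws the four
#' arm-level survival means from their sampling distributions
#' ([draw_psa_sample()]), recomputes the incremental QALYs, and pairs them
#' with the incremental cost, which is held constant across replicates along
#' with every other model parameter. The acceptability at the threshold is
#' the fraction of replicates with a positive QALY gain and an ICER below
#' the willingness-to-pay threshold.
#'
#' @param trial A [two_arm_trial()] with standard errors on all four means.
#' @param utilities A [health_state_utilities()].
#' @param costs A [cost_inputs()]; ignored when `delta_cost` is given.
#' @param config A [psa_config()].
#' @param delta_cost Optional fixed incremental cost; defaults to
#'   `incremental_cost(costs)$total_incremental_cost`.
#' @return Object of class `psa_result`: `draws` (data frame with columns
#'   `delta_qaly`, `delta_cost`, `icer`), `acceptability_at_threshold`,
#'   `threshold`, `n_iterations`, `seed`, `rejection_rate`.
#' @export
run_psa <- function(trial, utilities = health_state_utilities(),
                    costs = cost_inputs(), config = psa_config(),
                    delta_cost = NULL) {
  stopifnot(inherits(trial, "two_arm_trial"), inherits(config, "psa_config"))
  findings <- validate_trial(trial, psa_requested = TRUE)
  if (length(findings)) {
    stop("trial not ready for PSA: ", paste(findings, collapse = "; "),
         call. = FALSE)
  }
  if (is.null(delta_cost)) {
    delta_cost <- incremental_cost(costs)$total_incremental_cost
  }
  set.seed(config$seed)
  n <- config$n_iterations
  dq <- numeric(n)
  rejections <- 0L
  for (i in seq_len(n)) {
    rep_trial <- draw_psa_sample(trial)
    rejections <- rejections + attr(rep_trial, "rejections")
    dq[i] <- incremental_effects(rep_trial, utilities)$qalys
  }
  icer <- ifelse(dq != 0, delta_cost / dq, NA_real_)
  accept <- mean(dq > 0 & !is.na(icer) & icer < config$threshold)
  draws <- data.frame(delta_qaly = dq,
                      delta_cost = rep(delta_cost, n),
                      icer = icer)
  structure(list(draws = draws,
                 acceptability_at_threshold = accept,
                 threshold = config$threshold,
                 n_iterations = n,
                 seed = config$seed,
                 rejection_rate = rejections / (rejections + 2L * n)),
            class = "psa_result")
}

#' Acceptability of a PSA result at an arbitrary threshold
#'
#' Recomputes the cost-effectiveness acceptability (fraction of draws with
#' positive QALY gain and ICER below the threshold) from stored draws, e.g.
#' to trace an acceptability curve.
#'
#' @param psa A `psa_result`.
#' @param threshold Willingness-to-pay per QALY.
#' @return Fraction in \[0, 1\].
#' @export
acceptability_at <- function(psa, threshold) {
  stopifnot(inherits(psa, "psa_result"))
  d <- psa$draws
  mean(d$delta_qaly > 0 & !is.na(d$icer) & d$icer < threshold)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d simulated trials (seed %d)\n", x$n_iterations, x$seed))
  cat(sprintf("  P(cost-effective at EUR %.0f/QALY) = %.4f\n",
              x$threshold, x$acceptability_at_threshold))
  cat(sprintf("  rejection rate of infeasible draws: %.4f\n", x$rejection_rate))
  invisible(x)
}
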