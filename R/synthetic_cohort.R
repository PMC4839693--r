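# Seeded synthetic two-arm cohorts.
#
# The trial's individual patient data are not deposited, so patient-level
# OS/PFS are emulated with Weibull draws calibrated to the published
# arm-level means and medians. OS is built as PFS plus post-progression
# survival, which enforces PFS <= OS record by record.

DAYS_PER_MONTH <- 365.25 / 12

#' Fit a Weibull distribution to a mean and a median
#'
#' A two-parameter Weibull has mean scale * Gamma(1 + 1/shape) and median
#' scale * log(2)^(1/shape). Their ratio median/mean is strictly increasing
#' in the shape up to its maximum (about 1.0145 at shape 7.09) and falls back
#' towards 1 beyond it, so the shape is recovered uniquely by root-finding on
#' the increasing branch, and the scale follows from the mean. The
#' exponential identity median = mean * log(2) corresponds to shape 1.
#' Ratios above the branch maximum (a median more than ~1.4% above the mean)
#' are rejected as unachievable.
#'
#' @param mean_months,median_months Target mean and median (months, > 0).
#' @return Object of class `weibull_spec` with fields `shape` and
#'   `scale_months`.
#' @export
fit_weibull <- function(mean_months, median_months) {
  if (!is.finite(mean_months) || mean_months <= 0 ||
      !is.finite(median_months) || median_months <= 0) {
    stop("mean and median must be positive and finite", call. = FALSE)
  }
  target <- median_months / mean_months
  ratio_fn <- function(k) log(2)^(1 / k) / gamma(1 + 1 / k)
  lo <- 0.05
  hi <- 7.0925  # argmax of the ratio; the increasing branch ends here
  if (target <= ratio_fn(lo) || target >= ratio_fn(hi)) {
    stop(sprintf(
      "median/mean ratio %.4f outside the range achievable by a Weibull with shape in [%.2f, %.2f]",
      target, lo, hi), call. = FALSE)
  }
  root <- stats::uniroot(function(k) ratio_fn(k) - target,
                         lower = lo, upper = hi, tol = 1e-12)
  shape <- root$root
  scale <- mean_months / gamma(1 + 1 / shape)
  structure(list(shape = shape, scale_months = scale), class = "weibull_spec")
}

#' @export
print.weibull_spec <- function(x, ...) {
  cat(sprintf("Weibull(shape = %.4f, scale = %.4f months): mean %.4f, median %.4f\n",
              x$shape, x$scale_months, weibull_mean(x), weibull_median(x)))
  invisible(x)
}

#' Mean of a fitted Weibull specification
#' @param spec A `weibull_spec`.
#' @return Mean in months.
#' @export
weibull_mean <- function(spec) {
  spec$scale_months * gamma(1 + 1 / spec$shape)
}

#' Median of a fitted Weibull specification
#' @param spec A `weibull_spec`.
#' @return Median in months.
#' @export
weibull_median <- function(spec) {
  spec$scale_months * log(2)^(1 / spec$shape)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the trial the model is calibrated to: 30 control and 32
#' intervention patients, with the published arm-level means and medians as
#' calibration targets. PFS is drawn from a Weibull matched to the arm's PFS
#' mean and median; post-progression survival (PPS) from a Weibull with
#' configurable shape (default 1, i.e. exponential) matched to the arm's mean
#' OS minus mean PFS, so arm mean OS is matched in expectation.
#'
#' @param n_control,n_intervention Arm sizes.
#' @param control,intervention Named lists with elements `mean_os`,
#'   `mean_pfs`, `median_os`, `median_pfs` (months).
#' @param pps_shape Weibull shape for post-progression survival.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including the seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 30L, n_intervention = 32L,
                          control = list(mean_os = 8.6, mean_pfs = 5.6,
                                         median_os = 5.5, median_pfs = 3.6),
                          intervention = list(mean_os = 10.8, mean_pfs = 7.1,
                                              median_os = 9.5, median_pfs = 5.9),
                          pps_shape = 1,
                          seed = 1L) {
  n_control <- as.integer(n_control)
  n_intervention <- as.integer(n_intervention)
  if (is.na(n_control) || n_control < 2 || is.na(n_intervention) || n_intervention < 2) {
    stop("arm sizes must be integers >= 2", call. = FALSE)
  }
  for (arm in list(control, intervention)) {
    need <- c("mean_os", "mean_pfs", "median_os", "median_pfs")
    if (!all(need %in% names(arm))) {
      stop("arm targets must supply mean_os, mean_pfs, median_os, median_pfs",
           call. = FALSE)
    }
    if (arm$mean_pfs > arm$mean_os) stop("target mean PFS exceeds mean OS", call. = FALSE)
    if (arm$mean_os - arm$mean_pfs <= 0) {
      stop("mean OS must exceed mean PFS to calibrate post-progression survival",
           call. = FALSE)
    }
  }
  if (!is.finite(pps_shape) || pps_shape <= 0) {
    stop("pps_shape must be positive", call. = FALSE)
  }
  structure(list(n_control = n_control, n_intervention = n_intervention,
                 control = control, intervention = intervention,
                 pps_shape = pps_shape, seed = as.integer(seed)),
            class = "cohort_config")
}

weibull_scale_for_mean <- function(mean_months, shape) {
  mean_months / gamma(1 + 1 / shape)
}

#' Generate a seeded synthetic two-arm cohort
#'
#' Per arm, PFS is drawn from the Weibull fitted to the arm's PFS mean and
#' median; OS is PFS plus an independent post-progression draw whose mean is
#' the arm's mean OS minus mean PFS. PFS <= OS holds by construction, and the
#' same configuration (seed included) always yields the same cohort.
#'
#' @param config A [cohort_config()].
#' @return A validated `patient_records` data frame with `n_control +
#'   n_intervention` rows.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  one_arm <- function(n, targets, arm_label) {
    pfs_spec <- fit_weibull(targets$mean_pfs, targets$median_pfs)
    pps_scale <- weibull_scale_for_mean(targets$mean_os - targets$mean_pfs,
                                        config$pps_shape)
    pfs <- stats::rweibull(n, shape = pfs_spec$shape, scale = pfs_spec$scale_months)
    pps <- stats::rweibull(n, shape = config$pps_shape, scale = pps_scale)
    data.frame(arm = arm_label, pfs_months = pfs, os_months = pfs + pps,
               stringsAsFactors = FALSE)
  }
  records <- rbind(
    one_arm(config$n_control, config$control, "control"),
    one_arm(config$n_intervention, config$intervention, "intervention"))
  patient_records(records)
}

#' Per-patient cumulative cetuximab dose
#'
#' Each patient receives one loading administration plus weekly maintenance
#' administrations while on treatment; treatment lasts until progression or
#' the end of the maximum number of cycles, whichever comes first. Early
#' discontinuation is modelled in expectation: the maintenance count is
#' scaled by `1 - discontinuation_fraction`, so a fraction of 1 leaves the
#' loading dose only and 0 is full adherence. Dose per administration is the
#' scheduled mg/m2 times the body surface area.
#'
#' @param records Patient record table; only intervention-arm rows receive
#'   cetuximab and at least one must be present.
#' @param schedule A [dose_schedule()].
#' @param discontinuation_fraction Fraction of maintenance administrations
#'   lost to early discontinuation, in \[0, 1\].
#' @param bsa_m2 Body surface area in square metres (default 1.73).
#' @return Numeric vector of cumulative doses (mg), one per intervention-arm
#'   patient, in row order.
#' @export
generate_dosing <- function(records, schedule = dose_schedule(),
                            discontinuation_fraction = 0, bsa_m2 = 1.73) {
  records <- patient_records(records)
  stopifnot(inherits(schedule, "dose_schedule"))
  if (!is.finite(discontinuation_fraction) ||
      discontinuation_fraction < 0 || discontinuation_fraction > 1) {
    stop("discontinuation_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(bsa_m2) || bsa_m2 <= 0) stop("bsa_m2 must be positive", call. = FALSE)
  sub <- records[records$arm == "intervention", , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no intervention-arm records to dose", call. = FALSE)
  }
  n_maint <- maintenance_doses(sub$pfs_months, schedule)
  bsa_m2 * (schedule$loading_mg_per_m2 +
              (1 - discontinuation_fraction) * n_maint * schedule$maintenance_mg_per_m2)
}

# Full-adherence maintenance administrations for a vector of PFS times:
# weekly doses at days 7, 14, ... while still on treatment (progression or
# the 6-cycle cap, whichever is earlier).
maintenance_doses <- function(pfs_months, schedule) {
  treat_days <- pmin(pfs_months * DAYS_PER_MONTH,
                     schedule$max_cycles * schedule$cycle_length_days)
  pmax(0, floor(treat_days / schedule$maintenance_interval_days))
}
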