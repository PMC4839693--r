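# Shared fixtures and independent oracles.

# Small two-arm record table with hand-checkable statistics.
tiny_records <- function() {
  data.frame(
    arm = c("control", "control", "intervention", "intervention"),
    pfs_months = c(2, 4, 3, 5),
    os_months = c(4, 8, 6, 10),
    stringsAsFactors = FALSE)
}

# Independent bisection oracle for the Weibull shape given a median/mean
# ratio; deliberately avoids uniroot so it cannot share a code path with
# fit_weibull.
oracle_weibull_shape <- function(mean_months, median_months) {
  target <- median_months / mean_months
  ratio <- function(k) log(2)^(1 / k) / gamma(1 + 1 / k)
  lo <- 0.05
  hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (ratio(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Trial with arbitrary small standard errors attached, for PSA tests.
trial_with_small_ses <- function(se = 0.5) {
  two_arm_trial(
    control = survival_summary(
      n = 30, mean_os_months = 8.6, mean_pfs_months = 5.6,
      median_os_months = 5.5, median_pfs_months = 3.6,
      se_mean_os_months = se, se_mean_pfs_months = se),
    intervention = survival_summary(
      n = 32, mean_os_months = 10.8, mean_pfs_months = 7.1,
      median_os_months = 9.5, median_pfs_months = 5.9,
      se_mean_os_months = se, se_mean_pfs_months = se))
}

# The configured trial with standard errors taken from the seeded default
# synthetic cohorts, as the PSA uses them.
trial_with_synthetic_ses <- function(seed = 1) {
  records <- generate_cohort(cohort_config(seed = seed))
  trial <- default_trial()
  for (arm in c("control", "intervention")) {
    s <- summarize_cohort(records, arm)
    t <- trial[[arm]]
    trial[[arm]] <- survival_summary(
      n = t$n, mean_os_months = t$mean_os_months,
      mean_pfs_months = t$mean_pfs_months,
      median_os_months = t$median_os_months,
      median_pfs_months = t$median_pfs_months,
      se_mean_os_months = s$se_mean_os_months,
      se_mean_pfs_months = s$se_mean_pfs_months)
  }
  trial
}
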