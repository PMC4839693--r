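test_that("tornado rows follow the analytic behaviour of the model", {
  torn <- tornado()
  base_icer <- attr(torn, "base_icer")
  df <- as.data.frame(torn)

  # utility weight: QALYs scale linearly in u_pfs, so the ICER scales as
  # 1 / (1 +/- 0.1)
  urow <- df[df$parameter == "u_pfs", ]
  expect_equal(urow$icer_at_high, base_icer / 1.1, tolerance = 1e-9)
  expect_equal(urow$icer_at_low, base_icer / 0.9, tolerance = 1e-9)

  # drug price enters the cost linearly: closed-form range width
  prow <- df[df$parameter == "cetuximab_price_per_100mg", ]
  dq <- incremental_effects(default_trial())$qalys
  drug_uplifted <- drug_cost(6443, 237.20) * 1.42
  expect_equal(prow$icer_at_high - prow$icer_at_low,
               2 * 0.1 * drug_uplifted / dq, tolerance = 1e-9)

  # every unit-cost row is symmetric about the base ICER
  for (par in c("cetuximab_price_per_100mg", "mean_cumulative_dose_mg",
                "outpatient_visit_cost", "egfr_test_cost",
                "extra_visits_per_patient")) {
    row <- df[df$parameter == par, ]
    expect_equal((row$icer_at_low + row$icer_at_high) / 2, base_icer,
                 tolerance = 1e-9)
  }

  # the four trial survival means dominate the tornado
  expect_setequal(df$parameter[1:4],
                  c("control_mean_os", "control_mean_pfs",
                    "intervention_mean_os", "intervention_mean_pfs"))
  expect_true(all(diff(df$range_width) <= 1e-9))
  expect_false(any(df$infeasible))
})

test_that("infeasible perturbations are flagged, not dropped", {
  tight <- two_arm_trial(
    survival_summary(30, 8.6, 8.2),  # +10% PFS exceeds mean OS
    survival_summary(32, 10.8, 7.1))
  torn <- tornado(tight)
  df <- as.data.frame(torn)
  row <- df[df$parameter == "control_mean_pfs", ]
  expect_true(row$infeasible)
  expect_true(is.na(row$icer_at_high))
  expect_false(is.na(row$icer_at_low))
  expect_true("control_mean_pfs" %in% df$parameter)
})

test_that("PSA draws respect the sampling distribution and constraints", {
  # degenerate SEs return the base means unchanged
  degen <- trial_with_small_ses(se = 0)
  set.seed(1)
  d <- draw_psa_sample(degen)
  expect_equal(d$control$mean_os_months, 8.6)
  expect_equal(d$intervention$mean_pfs_months, 7.1)

  # determinism under a fixed seed
  trial <- trial_with_small_ses(se = 1.2)
  set.seed(99); a <- draw_psa_sample(trial)
  set.seed(99); b <- draw_psa_sample(trial)
  expect_equal(unclass(a$control), unclass(b$control))

  # sampled means spread with the specified standard error; arm means far
  # enough apart that the feasibility constraint never rejects
  far <- two_arm_trial(
    survival_summary(30, 20, 5, se_mean_os_months = 1.2,
                     se_mean_pfs_months = 1.2),
    survival_summary(32, 22, 6, se_mean_os_months = 1.2,
                     se_mean_pfs_months = 1.2))
  set.seed(7)
  os_draws <- replicate(4000, draw_psa_sample(far)$control$mean_os_months)
  expect_equal(sd(os_draws), 1.2, tolerance = 0.03)
  expect_equal(mean(os_draws), 20, tolerance = 0.01)

  # all draws satisfy the feasibility constraints
  set.seed(3)
  wide <- trial_with_small_ses(se = 3)
  for (i in 1:50) {
    s <- draw_psa_sample(wide)
    expect_gt(s$control$mean_pfs_months, 0)
    expect_lte(s$control$mean_pfs_months, s$control$mean_os_months)
    expect_lte(s$intervention$mean_pfs_months, s$intervention$mean_os_months)
  }

  expect_error(draw_psa_sample(default_trial()), "standard errors")
})

test_that("run_psa is reproducible and its acceptability behaves correctly", {
  trial <- trial_with_synthetic_ses(seed = 1)
  cfg <- psa_config(n_iterations = 400, seed = 21)
  a <- run_psa(trial, config = cfg)
  b <- run_psa(trial, config = cfg)
  expect_identical(a$draws, b$draws)
  expect_identical(a$acceptability_at_threshold, b$acceptability_at_threshold)

  # acceptability is monotone non-decreasing in the threshold
  acc <- vapply(c(1e4, 4e4, 1e5, 3e5, 1e6, 1e8), function(th) {
    acceptability_at(a, th)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))

  # a threshold above every draw's ICER (all QALY gains positive) gives 1
  tight <- trial_with_small_ses(se = 1e-3)
  high <- run_psa(tight, config = psa_config(n_iterations = 200, seed = 5),
                  delta_cost = 26459)
  expect_true(all(high$draws$delta_qaly > 0))
  expect_equal(acceptability_at(high, max(high$draws$icer) * 1.01), 1)

  # as SEs shrink, the draw cloud collapses onto the base-case point
  micro <- trial_with_small_ses(se = 1e-6)
  m <- run_psa(micro, config = psa_config(n_iterations = 100, seed = 2))
  expect_equal(max(abs(m$draws$delta_qaly - 0.1040625)), 0, tolerance = 1e-6)

  # changing the seed changes the draws
  c2 <- run_psa(trial, config = psa_config(n_iterations = 400, seed = 22))
  expect_false(identical(a$draws$delta_qaly, c2$draws$delta_qaly))

  expect_error(run_psa(default_trial()), "standard errors")
})
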