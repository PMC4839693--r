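test_that("fit_weibull recovers shape and scale from mean and median", {
  # exponential identity: median = mean * log(2) <=> shape 1, scale = mean
  spec <- fit_weibull(7, 7 * log(2))
  expect_equal(spec$shape, 1, tolerance = 1e-8)
  expect_equal(spec$scale_months, 7, tolerance = 1e-8)

  # frozen values from an independent bisection oracle on the monotone
  # median/mean ratio (see helper-fixtures.R)
  ctrl_os <- fit_weibull(8.6, 5.5)
  expect_equal(ctrl_os$shape, 0.9106350419, tolerance = 1e-6)
  expect_lt(ctrl_os$shape, 1)  # ratio 0.640 < log(2)
  intv_os <- fit_weibull(10.8, 9.5)
  expect_equal(intv_os$shape, 1.5599247752, tolerance = 1e-6)
  expect_gt(intv_os$shape, 1.4)
  expect_lt(intv_os$shape, 1.7)

  expect_equal(ctrl_os$shape, oracle_weibull_shape(8.6, 5.5), tolerance = 1e-8)
  expect_equal(fit_weibull(5.6, 3.6)$shape, oracle_weibull_shape(5.6, 3.6),
               tolerance = 1e-8)

  # fitted specs reproduce their calibration targets
  expect_equal(weibull_mean(ctrl_os), 8.6, tolerance = 1e-8)
  expect_equal(weibull_median(ctrl_os), 5.5, tolerance = 1e-8)
})

test_that("fit_weibull round-trips its own mean/median across a shape grid", {
  # shapes across the increasing branch of the median/mean ratio
  for (shape in c(0.3, 0.7, 1, 1.8, 4, 6.5)) {
    for (scale in c(0.5, 6, 40)) {
      spec <- structure(list(shape = shape, scale_months = scale),
                        class = "weibull_spec")
      refit <- fit_weibull(weibull_mean(spec), weibull_median(spec))
      expect_equal(refit$shape, shape, tolerance = 1e-8)
      expect_equal(refit$scale_months, scale, tolerance = 1e-8)
    }
  }
})

test_that("fit_weibull rejects unachievable median/mean ratios", {
  # ratio above the branch maximum (~1.0145)
  expect_error(fit_weibull(5, 5.2), "outside the range")
  expect_error(fit_weibull(-1, 2), "positive")
  expect_error(fit_weibull(3, 0), "positive")
})

test_that("generate_cohort is seeded, valid, and hits its calibration targets", {
  cfg <- cohort_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 62)
  expect_equal(sum(a$arm == "control"), 30)
  expect_true(all(a$pfs_months <= a$os_months))
  expect_true(all(a$pfs_months >= 0))

  # convergence of the empirical statistics to the targets at large n
  big <- generate_cohort(cohort_config(n_control = 10000,
                                       n_intervention = 10000, seed = 5))
  ctrl <- big[big$arm == "control", ]
  intv <- big[big$arm == "intervention", ]
  expect_equal(mean(ctrl$os_months), 8.6, tolerance = 0.02)
  expect_equal(mean(ctrl$pfs_months), 5.6, tolerance = 0.02)
  expect_equal(mean(intv$os_months), 10.8, tolerance = 0.02)
  expect_equal(mean(intv$pfs_months), 7.1, tolerance = 0.02)
  expect_equal(median(ctrl$pfs_months), 3.6, tolerance = 0.04)
  expect_equal(median(intv$pfs_months), 5.9, tolerance = 0.04)
})

test_that("cohort configuration rejects inadmissible targets", {
  expect_error(cohort_config(n_control = 1), ">= 2")
  expect_error(
    cohort_config(control = list(mean_os = 5, mean_pfs = 6,
                                 median_os = 4, median_pfs = 3)),
    "mean PFS exceeds mean OS")
})

test_that("generate_dosing follows the schedule and the discontinuation model", {
  recs <- generate_cohort(cohort_config(seed = 2))
  sched <- dose_schedule()

  # full discontinuation: loading dose only, 400 mg/m2 x 1.73 m2 = 692 mg
  d1 <- generate_dosing(recs, sched, discontinuation_fraction = 1, bsa_m2 = 1.73)
  expect_equal(d1, rep(692, sum(recs$arm == "intervention")))

  # mean dose decreases monotonically in the discontinuation fraction
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                  function(f) mean(generate_dosing(recs, sched, f)), numeric(1))
  expect_true(all(diff(means) < 0))

  # a patient progressing before the first maintenance dose gets loading only
  one <- data.frame(arm = "intervention", pfs_months = 0.1, os_months = 1)
  expect_equal(generate_dosing(one, sched, 0, bsa_m2 = 1.73), 692)

  # treatment is capped at 6 cycles of 29 days = 174 days -> 24 weekly doses
  long <- data.frame(arm = "intervention", pfs_months = 36, os_months = 40)
  expect_equal(generate_dosing(long, sched, 0, bsa_m2 = 1.73),
               1.73 * (400 + 24 * 250))

  expect_error(generate_dosing(recs[recs$arm == "control", ], sched, 0),
               "no intervention-arm")
  expect_error(generate_dosing(recs, sched, 1.2), "\\[0, 1\\]")
})
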