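test_that("cost components match hand arithmetic", {
  # 64.43 vials x 237.20
  expect_equal(drug_cost(6443, 237.20), 15282.796)
  expect_equal(drug_cost(0, 237.20), 0)
  expect_equal(drug_cost(100, 207.00), 207)
  expect_error(drug_cost(-1, 200), "non-negative")

  expect_equal(screening_cost_per_treated(750, 0.60), 1250)
  expect_equal(screening_cost_per_treated(750, 1), 750)
  expect_equal(screening_cost_per_treated(0, 0.6), 0)
  expect_error(screening_cost_per_treated(750, 0), "positive")

  expect_equal(visit_cost(8, 251), 2008)
  expect_equal(visit_cost(0, 251), 0)
  expect_equal(visit_cost(1, 251), 251)

  expect_equal(index_price(100, 1), 100)
  expect_equal(index_price(207, 1.037), 207 * 1.037)
  expect_equal(index_price(0, 2), 0)
  expect_error(index_price(100, 0), "positive")
})

test_that("incremental cost reproduces the base case and its breakdown sums", {
  br <- incremental_cost(cost_inputs())
  expect_equal(br$drug_cost, 15282.796)
  expect_equal(br$visit_cost, 2008)
  expect_equal(br$screening_cost, 1250)
  expect_equal(br$total_incremental_cost, 18540.796 * 1.42)
  # within 0.5% of the published EUR 26,459
  expect_equal(br$total_incremental_cost, 26459, tolerance = 0.005)

  # components sum: total / uplift / index = drug + visits + screening
  expect_equal(br$total_incremental_cost / 1.42,
               br$drug_cost + br$visit_cost + br$screening_cost,
               tolerance = 1e-12)
  expect_equal(br$uplift, 18540.796 * 0.42, tolerance = 1e-9)

  # hand-summed degenerate case: no uplift, one visit, no drug, all positive
  plain <- incremental_cost(cost_inputs(
    mean_cumulative_dose_mg = 0, extra_visits_per_patient = 1,
    egfr_positive_fraction = 1, overhead_fraction = 0, housing_fraction = 0))
  expect_equal(plain$total_incremental_cost, 750 + 251)

  zero <- incremental_cost(cost_inputs(
    cetuximab_price_per_100mg = 0, outpatient_visit_cost = 0,
    egfr_test_cost = 0))
  expect_equal(zero$total_incremental_cost, 0)
})

test_that("total incremental cost is linear in each unit cost", {
  total_at <- function(...) {
    incremental_cost(do.call(cost_inputs, list(...)))$total_incremental_cost
  }
  base <- total_at()
  for (par in c("cetuximab_price_per_100mg", "outpatient_visit_cost",
                "egfr_test_cost")) {
    args0 <- list(); args0[[par]] <- 0
    args2 <- list(); args2[[par]] <- 2 * cost_inputs()[[par]]
    at0 <- do.call(total_at, args0)
    at2 <- do.call(total_at, args2)
    # doubling a unit cost adds exactly the component it scales
    expect_equal(at2 - base, base - at0, tolerance = 1e-9)
  }
})

test_that("discontinuation calibration hits the target dose by re-simulation", {
  recs <- generate_cohort(cohort_config(seed = 1))
  sched <- dose_schedule()
  full <- mean(generate_dosing(recs, sched, 0))
  loading_only <- mean(generate_dosing(recs, sched, 1))

  expect_equal(calibrate_discontinuation(sched, recs,
                                         target_mean_dose_mg = full), 0)
  expect_equal(calibrate_discontinuation(sched, recs,
                                         target_mean_dose_mg = loading_only), 1)

  f <- calibrate_discontinuation(sched, recs, target_mean_dose_mg = 6443)
  expect_gt(f, 0)
  expect_lt(f, 1)
  resim <- mean(generate_dosing(recs, sched, f))
  expect_equal(resim, 6443, tolerance = 0.005)

  expect_error(
    calibrate_discontinuation(sched, recs, target_mean_dose_mg = full + 1),
    "achievable range")
})

test_that("cost input validation names the offence", {
  expect_error(cost_inputs(egfr_positive_fraction = 0), "\\(0, 1\\]")
  expect_error(cost_inputs(vat_factor = 0.9), "at least 1")
  expect_error(cost_inputs(cetuximab_price_per_100mg = -5), "non-negative")
  expect_error(cost_inputs(price_index_factor = -1), "positive")
  expect_error(dose_schedule(loading_mg_per_m2 = 200), "at least the maintenance")
})
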