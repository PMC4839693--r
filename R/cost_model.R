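# Incremental direct medical cost per treated patient.
#
# Only cost items that differ between arms are modelled: cetuximab
# acquisition, additional day-treatment/outpatient visits, and EGFR screening
# amortized over the biomarker-positive fraction; the cisplatin/5-FU backbone
# is identical in both arms and cancels. An overhead (35.5%) and housing /
# depreciation (6.5%) uplift is applied to the component sum, followed by an
# optional consumer-price-index factor. Money is kept unrounded internally;
# rounding to cents or whole euros happens only in reports.

#' Cetuximab dosing schedule
#'
#' @param loading_mg_per_m2 First administration (default 400 mg/m2).
#' @param maintenance_mg_per_m2 Weekly maintenance administration (250 mg/m2).
#' @param maintenance_interval_days Days between maintenance doses (7).
#' @param cycle_length_days Chemotherapy cycle length (29 days).
#' @param max_cycles Maximum number of cycles (6).
#' @return Object of class `dose_schedule`.
#' @export
dose_schedule <- function(loading_mg_per_m2 = 400,
                          maintenance_mg_per_m2 = 250,
                          maintenance_interval_days = 7,
                          cycle_length_days = 29,
                          max_cycles = 6) {
  vals <- c(loading_mg_per_m2, maintenance_mg_per_m2,
            maintenance_interval_days, cycle_length_days, max_cycles)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all schedule fields must be positive", call. = FALSE)
  }
  if (loading_mg_per_m2 < maintenance_mg_per_m2) {
    stop("loading dose must be at least the maintenance dose", call. = FALSE)
  }
  structure(list(loading_mg_per_m2 = loading_mg_per_m2,
                 maintenance_mg_per_m2 = maintenance_mg_per_m2,
                 maintenance_interval_days = maintenance_interval_days,
                 cycle_length_days = cycle_length_days,
                 max_cycles = max_cycles),
            class = "dose_schedule")
}

#' Unit costs and cost-model parameters
#'
#' Defaults reproduce the published base case at the 2009 price level:
#' cetuximab EUR 237.20 per 100 mg (the 2007 price, EUR 207, can be
#' substituted together with a price-index factor), an outpatient/day
#' treatment visit at EUR 251, EGFR testing at EUR 750 with 60% of screened
#' patients positive, overhead 35.5% and housing/depreciation 6.5%, and a
#' mean cumulative cetuximab dose of 6,443 mg per treated patient. The price
#' is treated as VAT-inclusive (`vat_factor` 1) and eight additional
#' day-treatment visits per patient are assumed; both are reconstructions of
#' unpublished model detail, exposed as parameters (see the methods
#' vignette).
#'
#' @param cetuximab_price_per_100mg Drug price per 100 mg vial equivalent.
#' @param vat_factor Multiplier on the drug price (>= 1); default 1.
#' @param outpatient_visit_cost Cost of one visit.
#' @param extra_visits_per_patient Additional visits attributable to weekly
#'   cetuximab administration not coinciding with chemotherapy visits.
#' @param egfr_test_cost Cost of one EGFR expression test.
#' @param egfr_positive_fraction Fraction of screened patients eligible
#'   (in (0, 1]).
#' @param overhead_fraction,housing_fraction Uplift fractions applied to the
#'   component sum.
#' @param price_index_factor Consumer-price-index conversion factor (> 0).
#' @param mean_cumulative_dose_mg Mean cumulative cetuximab dose per treated
#'   patient (mg).
#' @return Object of class `cost_inputs`.
#' @export
cost_inputs <- function(cetuximab_price_per_100mg = 237.20,
                        vat_factor = 1.0,
                        outpatient_visit_cost = 251,
                        extra_visits_per_patient = 8,
                        egfr_test_cost = 750,
                        egfr_positive_fraction = 0.60,
                        overhead_fraction = 0.355,
                        housing_fraction = 0.065,
                        price_index_factor = 1.0,
                        mean_cumulative_dose_mg = 6443) {
  money <- c(cetuximab_price_per_100mg, outpatient_visit_cost,
             egfr_test_cost, mean_cumulative_dose_mg, extra_visits_per_patient)
  if (any(!is.finite(money)) || any(money < 0)) {
    stop("money amounts, visit counts and doses must be finite and non-negative",
         call. = FALSE)
  }
  if (!is.finite(vat_factor) || vat_factor < 1) {
    stop("vat_factor must be at least 1", call. = FALSE)
  }
  if (!is.finite(egfr_positive_fraction) ||
      egfr_positive_fraction <= 0 || egfr_positive_fraction > 1) {
    stop("egfr_positive_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(overhead_fraction) || overhead_fraction < 0 ||
      !is.finite(housing_fraction) || housing_fraction < 0) {
    stop("uplift fractions must be non-negative", call. = FALSE)
  }
  if (!is.finite(price_index_factor) || price_index_factor <= 0) {
    stop("price_index_factor must be positive", call. = FALSE)
  }
  structure(list(cetuximab_price_per_100mg = cetuximab_price_per_100mg,
                 vat_factor = vat_factor,
                 outpatient_visit_cost = outpatient_visit_cost,
                 extra_visits_per_patient = extra_visits_per_patient,
                 egfr_test_cost = egfr_test_cost,
                 egfr_positive_fraction = egfr_positive_fraction,
                 overhead_fraction = overhead_fraction,
                 housing_fraction = housing_fraction,
                 price_index_factor = price_index_factor,
                 mean_cumulative_dose_mg = mean_cumulative_dose_mg),
            class = "cost_inputs")
}

#' Drug acquisition cost for a cumulative dose
#'
#' @param mean_cumulative_dose_mg Cumulative dose in mg.
#' @param price_per_100mg Price per 100 mg.
#' @param vat_factor Multiplier on the price (default 1).
#' @return `(dose/100) * price * vat_factor`.
#' @export
drug_cost <- function(mean_cumulative_dose_mg, price_per_100mg, vat_factor = 1) {
  if (mean_cumulative_dose_mg < 0 || price_per_100mg < 0 || vat_factor < 0) {
    stop("drug cost inputs must be non-negative", call. = FALSE)
  }
  (mean_cumulative_dose_mg / 100) * price_per_100mg * vat_factor
}

#' EGFR screening cost amortized per treated patient
#'
#' All candidates are screened but only the biomarker-positive fraction is
#' treated, so each treated patient carries the test cost of
#' `1 / positive_fraction` screened patients.
#'
#' @param test_cost Cost of one test.
#' @param positive_fraction Fraction of screened patients positive, in (0, 1].
#' @return `test_cost / positive_fraction`.
#' @export
screening_cost_per_treated <- function(test_cost, positive_fraction) {
  if (!is.finite(positive_fraction) || positive_fraction <= 0) {
    stop("positive_fraction must be positive", call. = FALSE)
  }
  if (test_cost < 0) stop("test_cost must be non-negative", call. = FALSE)
  test_cost / positive_fraction
}

#' Cost of additional day-treatment visits
#'
#' @param extra_visits_per_patient Number of additional visits.
#' @param outpatient_visit_cost Cost per visit.
#' @return Product of the two.
#' @export
visit_cost <- function(extra_visits_per_patient, outpatient_visit_cost) {
  if (extra_visits_per_patient < 0 || outpatient_visit_cost < 0) {
    stop("visit inputs must be non-negative", call. = FALSE)
  }
  extra_visits_per_patient * outpatient_visit_cost
}

#' Price-year indexation
#'
#' @param amount Money amount.
#' @param price_index_factor Conversion factor (> 0).
#' @return `amount * price_index_factor`.
#' @export
index_price <- function(amount, price_index_factor) {
  if (!is.finite(price_index_factor) || price_index_factor <= 0) {
    stop("price_index_factor must be positive", call. = FALSE)
  }
  amount * price_index_factor
}

#' Mean incremental cost per treated patient
#'
#' Sums the drug, visit and screening components, applies the overhead +
#' housing uplift `(1 + overhead_fraction + housing_fraction)` (1.42 at the
#' defaults) and the price-index factor.
#'
#' @param inputs A [cost_inputs()] object.
#' @return Object of class `cost_breakdown` with the components, the uplift
#'   amount (difference between the uplifted and raw component sum before
#'   indexation) and `total_incremental_cost`.
#' @export
incremental_cost <- function(inputs = cost_inputs()) {
  stopifnot(inherits(inputs, "cost_inputs"))
  drug <- drug_cost(inputs$mean_cumulative_dose_mg,
                    inputs$cetuximab_price_per_100mg,
                    inputs$vat_factor)
  visits <- visit_cost(inputs$extra_visits_per_patient,
                       inputs$outpatient_visit_cost)
  screening <- screening_cost_per_treated(inputs$egfr_test_cost,
                                          inputs$egfr_positive_fraction)
  pre_uplift <- drug + visits + screening
  uplift_factor <- 1 + inputs$overhead_fraction + inputs$housing_fraction
  total <- index_price(pre_uplift * uplift_factor, inputs$price_index_factor)
  structure(list(drug_cost = drug,
                 visit_cost = visits,
                 screening_cost = screening,
                 uplift = pre_uplift * (uplift_factor - 1),
                 total_incremental_cost = total),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("Incremental cost per treated patient (EUR)\n")
  cat(sprintf("  drug       %10.2f\n", x$drug_cost))
  cat(sprintf("  visits     %10.2f\n", x$visit_cost))
  cat(sprintf("  screening  %10.2f\n", x$screening_cost))
  cat(sprintf("  uplift     %10.2f\n", x$uplift))
  cat(sprintf("  total      %10.2f\n", x$total_incremental_cost))
  invisible(x)
}

#' Calibrate the discontinuation fraction to a target mean dose
#'
#' Finds the discontinuation fraction at which the cohort's mean cumulative
#' cetuximab dose (see [generate_dosing()]) equals the target, by monotone
#' root-finding between the two extremes: full adherence (fraction 0) and
#' loading dose only (fraction 1). The target must be achievable between
#' those extremes for the given cohort.
#'
#' @param schedule A [dose_schedule()].
#' @param cohort Patient record table containing intervention-arm rows.
#' @param bsa_m2 Body surface area assumption (m2).
#' @param target_mean_dose_mg Target cohort mean cumulative dose (default
#'   6,443 mg).
#' @return The calibrated fraction in \[0, 1\].
#' @export
calibrate_discontinuation <- function(schedule = dose_schedule(), cohort,
                                      bsa_m2 = 1.73,
                                      target_mean_dose_mg = 6443) {
  mean_dose_at <- function(f) {
    mean(generate_dosing(cohort, schedule, discontinuation_fraction = f,
                         bsa_m2 = bsa_m2))
  }
  full <- mean_dose_at(0)
  loading_only <- mean_dose_at(1)
  if (target_mean_dose_mg > full || target_mean_dose_mg < loading_only) {
    stop(sprintf(
      "target mean dose %.1f mg outside the achievable range [%.1f, %.1f] mg for this cohort",
      target_mean_dose_mg, loading_only, full), call. = FALSE)
  }
  if (target_mean_dose_mg == full) return(0)
  if (target_mean_dose_mg == loading_only) return(1)
  stats::uniroot(function(f) mean_dose_at(f) - target_mean_dose_mg,
                 lower = 0, upper = 1, tol = 1e-12)$root
}
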