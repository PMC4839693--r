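# Flat key-value configuration and the end-to-end pipeline runner.
#
# Every model constant is a named key with its base-case default, so a config
# file documents the full reconstruction. Unknown keys are rejected rather
# than ignored.

config_defaults <- function() {
  list(
    # trial arm summaries (months)
    n_control = 30L, n_intervention = 32L,
    control_mean_os = 8.6, control_mean_pfs = 5.6,
    control_median_os = 5.5, control_median_pfs = 3.6,
    intervention_mean_os = 10.8, intervention_mean_pfs = 7.1,
    intervention_median_os = 9.5, intervention_median_pfs = 5.9,
    # optional patient-level input; overrides the summaries above when set
    cohort_csv = NA_character_,
    # utilities
    u_pfs = 0.675, u_asymptomatic_alt = 0.77,
    # costs
    cetuximab_price_per_100mg = 237.20, vat_factor = 1.0,
    outpatient_visit_cost = 251, extra_visits_per_patient = 8,
    egfr_test_cost = 750, egfr_positive_fraction = 0.60,
    overhead_fraction = 0.355, housing_fraction = 0.065,
    price_index_factor = 1.0, mean_cumulative_dose_mg = 6443,
    # dosing schedule
    loading_mg_per_m2 = 400, maintenance_mg_per_m2 = 250,
    maintenance_interval_days = 7, cycle_length_days = 29, max_cycles = 6,
    bsa_m2 = 1.73, pps_shape = 1,
    # analysis settings
    psa_iterations = 1000L, wtp_threshold_per_qaly = 40000,
    time_horizon_years = 0.9,  # informational; the model is undiscounted
    seed = 1L)
}

#' Load a run configuration from a flat key-value file
#'
#' The file is YAML restricted to a flat mapping of scalar keys; every key
#' has a documented base-case default (see [default_run_config()]), so an
#' empty file yields the base case. Unknown keys, type mismatches and
#' invariant violations raise an error naming the offending key. The
#' effective post-default configuration is echoed via `message()`.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @param quiet Suppress the configuration echo.
#' @return Object of class `run_config`: validated sub-objects `trial`,
#'   `utilities`, `costs`, `schedule`, `psa`, `decision`, plus the raw
#'   key-value list as `values`.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  values <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user) || (length(user) && is.null(names(user)))) {
      stop("config must be a flat mapping of key: value pairs", call. = FALSE)
    }
    unknown <- setdiff(names(user), names(values))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (key in names(user)) {
      v <- user[[key]]
      if (length(v) != 1) {
        stop("config key '", key, "' must be a single scalar", call. = FALSE)
      }
      if (key == "cohort_csv") {
        values[[key]] <- as.character(v)
        next
      }
      if (!is.numeric(v)) {
        stop("config key '", key, "' must be numeric", call. = FALSE)
      }
      values[[key]] <- if (is.integer(values[[key]])) as.integer(v) else as.numeric(v)
    }
  }
  cfg <- build_run_config(values)
  if (!quiet) {
    message("effective configuration:\n",
            paste(sprintf("  %s: %s", names(values),
                          vapply(values, format, character(1))),
                  collapse = "\n"))
  }
  cfg
}

#' Base-case run configuration
#'
#' @return The `run_config` produced by all defaults (no file).
#' @export
default_run_config <- function() {
  build_run_config(config_defaults())
}

build_run_config <- function(values) {
  with_key <- function(key, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("config key '%s': %s", key, conditionMessage(e)),
           call. = FALSE)
    })
  }
  utilities <- with_key("u_pfs", health_state_utilities(
    u_pfs = values$u_pfs, u_asymptomatic_alt = values$u_asymptomatic_alt))
  costs <- with_key("cost inputs", cost_inputs(
    cetuximab_price_per_100mg = values$cetuximab_price_per_100mg,
    vat_factor = values$vat_factor,
    outpatient_visit_cost = values$outpatient_visit_cost,
    extra_visits_per_patient = values$extra_visits_per_patient,
    egfr_test_cost = values$egfr_test_cost,
    egfr_positive_fraction = values$egfr_positive_fraction,
    overhead_fraction = values$overhead_fraction,
    housing_fraction = values$housing_fraction,
    price_index_factor = values$price_index_factor,
    mean_cumulative_dose_mg = values$mean_cumulative_dose_mg))
  schedule <- with_key("dose schedule", dose_schedule(
    loading_mg_per_m2 = values$loading_mg_per_m2,
    maintenance_mg_per_m2 = values$maintenance_mg_per_m2,
    maintenance_interval_days = values$maintenance_interval_days,
    cycle_length_days = values$cycle_length_days,
    max_cycles = values$max_cycles))
  cohort_cfg <- with_key("cohort targets", cohort_config(
    n_control = values$n_control, n_intervention = values$n_intervention,
    control = list(mean_os = values$control_mean_os,
                   mean_pfs = values$control_mean_pfs,
                   median_os = values$control_median_os,
                   median_pfs = values$control_median_pfs),
    intervention = list(mean_os = values$intervention_mean_os,
                        mean_pfs = values$intervention_mean_pfs,
                        median_os = values$intervention_median_os,
                        median_pfs = values$intervention_median_pfs),
    pps_shape = values$pps_shape, seed = values$seed))
  trial <- with_key("trial summaries", two_arm_trial(
    control = survival_summary(
      n = values$n_control,
      mean_os_months = values$control_mean_os,
      mean_pfs_months = values$control_mean_pfs,
      median_os_months = values$control_median_os,
      median_pfs_months = values$control_median_pfs),
    intervention = survival_summary(
      n = values$n_intervention,
      mean_os_months = values$intervention_mean_os,
      mean_pfs_months = values$intervention_mean_pfs,
      median_os_months = values$intervention_median_os,
      median_pfs_months = values$intervention_median_pfs)))
  psa <- with_key("psa settings", psa_config(
    n_iterations = values$psa_iterations, seed = values$seed,
    threshold = values$wtp_threshold_per_qaly))
  decision <- with_key("wtp_threshold_per_qaly",
                       decision_config(values$wtp_threshold_per_qaly))
  structure(list(values = values, trial = trial, utilities = utilities,
                 costs = costs, schedule = schedule, cohort = cohort_cfg,
                 psa = psa, decision = decision,
                 bsa_m2 = values$bsa_m2, seed = values$seed),
            class = "run_config")
}

# Attach synthetic-cohort standard errors (and, when patient-level data are
# supplied, the full summaries) to the configured trial.
trial_with_ses <- function(config) {
  if (!is.na(config$values$cohort_csv)) {
    records <- read_patient_table(config$values$cohort_csv)
    return(two_arm_trial(control = summarize_cohort(records, "control"),
                         intervention = summarize_cohort(records, "intervention")))
  }
  records <- generate_cohort(config$cohort)
  trial <- config$trial
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

#' Run the full analysis pipeline
#'
#' Executes the base case, the zero-drug-price scenario, the tornado
#' analysis and the PSA, and writes `base_case.json`, `tornado.csv`,
#' `psa_draws.csv`, `psa_summary.json` and a plain-text `summary.txt` into
#' the output directory. Standard errors for the PSA come from the seeded
#' synthetic cohort (or from patient-level data when `cohort_csv` is set).
#' Any stage failure aborts with a stage-labelled message and removes
#' partially written outputs.
#'
#' @param config A `run_config` (see [load_config()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with elements `base_case`, `zero_drug`,
#'   `tornado`, `psa`, `files`.
#' @export
run_all <- function(config = default_run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  written <- character(0)
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
    })
  }
  out <- function(name) file.path(out_dir, name)

  bc <- stage("base-case", base_case(config$trial, config$utilities, config$costs))
  zd <- stage("zero-drug-scenario",
              zero_drug_scenario(config$costs, config$trial, config$utilities))
  torn <- stage("tornado", tornado(config$trial, config$utilities, config$costs))
  psa <- stage("psa", {
    trial_se <- trial_with_ses(config)
    run_psa(trial_se, config$utilities, config$costs, config$psa)
  })

  stage("write-outputs", {
    jsonlite::write_json(
      list(delta_cost = bc$delta_cost, delta_ly = bc$delta_ly,
           delta_qaly = bc$delta_qaly, icer_per_qaly = bc$icer_per_qaly,
           quadrant = bc$quadrant,
           zero_drug_icer_per_qaly = zd$icer_per_qaly,
           nmb_at_threshold = net_monetary_benefit(
             bc$delta_cost, bc$delta_qaly,
             config$decision$wtp_threshold_per_qaly)),
      out("base_case.json"), auto_unbox = TRUE, digits = NA)
    written <<- c(written, out("base_case.json"))
    utils::write.csv(as.data.frame(torn), out("tornado.csv"),
                     row.names = FALSE, quote = FALSE)
    written <<- c(written, out("tornado.csv"))
    utils::write.csv(psa$draws, out("psa_draws.csv"),
                     row.names = FALSE, quote = FALSE)
    written <<- c(written, out("psa_draws.csv"))
    jsonlite::write_json(
      list(acceptability_at_threshold = psa$acceptability_at_threshold,
           threshold = psa$threshold, n_iterations = psa$n_iterations,
           seed = psa$seed, rejection_rate = psa$rejection_rate),
      out("psa_summary.json"), auto_unbox = TRUE, digits = NA)
    written <<- c(written, out("psa_summary.json"))
    writeLines(c(
      "Cost-utility analysis summary",
      sprintf("Incremental life-years:      %.4f", bc$delta_ly),
      sprintf("Incremental QALYs:           %.4f", bc$delta_qaly),
      sprintf("Incremental cost:            EUR %.0f", bc$delta_cost),
      sprintf("ICER:                        EUR %.0f per QALY", bc$icer_per_qaly),
      sprintf("Zero-drug-price ICER:        EUR %.0f per QALY", zd$icer_per_qaly),
      sprintf("P(cost-effective at EUR %.0f/QALY): %.4f",
              psa$threshold, psa$acceptability_at_threshold)),
      out("summary.txt"))
    written <<- c(written, out("summary.txt"))
  })

  invisible(list(base_case = bc, zero_drug = zd, tornado = torn, psa = psa,
                 files = written))
}
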