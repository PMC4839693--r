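# Arm-level and patient-level survival inputs.
#
# Survival times are stored in MONTHS in every input container; conversion to
# years happens in one place only, inside the effect computations
# (see arm_effects), so that unit mistakes cannot creep in elsewhere.

ARM_LEVELS <- c("control", "intervention")

#' Validate a patient-level record table
#'
#' A patient record table is a data frame with one row per patient and columns
#' `arm` (one of `"control"` or `"intervention"`), `pfs_months` and
#' `os_months`. Progression-free survival may not exceed overall survival, and
#' both must be finite and non-negative.
#'
#' @param records Data frame with columns `arm`, `pfs_months`, `os_months`.
#' @return The validated data frame, invisibly classed as `patient_records`,
#'   with `arm` as a factor over the two trial arms.
#' @export
patient_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("arm", "pfs_months", "os_months")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("patient record table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_arm <- !records$arm %in% ARM_LEVELS
  if (any(bad_arm)) {
    stop("unknown arm label(s) at record(s) ",
         paste(which(bad_arm), collapse = ", "),
         " (expected 'control' or 'intervention')", call. = FALSE)
  }
  pfs <- records$pfs_months
  os <- records$os_months
  bad_num <- !is.finite(pfs) | !is.finite(os) | pfs < 0 | os < 0
  if (any(bad_num)) {
    stop("non-finite or negative survival time(s) at record(s) ",
         paste(which(bad_num), collapse = ", "), call. = FALSE)
  }
  bad_order <- pfs > os
  if (any(bad_order)) {
    stop("PFS exceeds OS at record(s) ",
         paste(which(bad_order), collapse = ", "), call. = FALSE)
  }
  records$arm <- factor(as.character(records$arm), levels = ARM_LEVELS)
  class(records) <- unique(c("patient_records", class(records)))
  invisible(records)
}

#' Arm-level survival summary
#'
#' Container for the arm-level statistics the cost-utility model consumes:
#' mean and median OS and PFS in months, the arm size, and (optionally) the
#' standard errors of the two means, which drive the probabilistic
#' sensitivity analysis.
#'
#' @param n Arm size (positive integer; at least 2 when standard errors are
#'   supplied).
#' @param mean_os_months,mean_pfs_months Arm means in months.
#' @param median_os_months,median_pfs_months Arm medians in months.
#' @param se_mean_os_months,se_mean_pfs_months Standard errors of the means
#'   (months); `NA` when unknown.
#' @return An object of class `survival_summary`.
#' @export
survival_summary <- function(n, mean_os_months, mean_pfs_months,
                             median_os_months = NA_real_,
                             median_pfs_months = NA_real_,
                             se_mean_os_months = NA_real_,
                             se_mean_pfs_months = NA_real_) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("arm size n must be a positive integer", call. = FALSE)
  if (!is.finite(mean_os_months) || !is.finite(mean_pfs_months) ||
      mean_os_months < 0 || mean_pfs_months < 0) {
    stop("mean survival times must be finite and non-negative", call. = FALSE)
  }
  if (mean_pfs_months > mean_os_months) {
    stop("mean PFS exceeds mean OS", call. = FALSE)
  }
  if (!is.na(median_os_months) && !is.na(median_pfs_months) &&
      median_pfs_months > median_os_months) {
    stop("median PFS exceeds median OS", call. = FALSE)
  }
  has_se <- !is.na(se_mean_os_months) || !is.na(se_mean_pfs_months)
  if (has_se && n < 2) {
    stop("n must be at least 2 when standard errors are populated", call. = FALSE)
  }
  if ((!is.na(se_mean_os_months) && se_mean_os_months < 0) ||
      (!is.na(se_mean_pfs_months) && se_mean_pfs_months < 0)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  structure(
    list(n = n,
         mean_os_months = mean_os_months,
         mean_pfs_months = mean_pfs_months,
         median_os_months = median_os_months,
         median_pfs_months = median_pfs_months,
         se_mean_os_months = se_mean_os_months,
         se_mean_pfs_months = se_mean_pfs_months),
    class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf("Survival summary (n = %d)\n", x$n))
  cat(sprintf("  OS : mean %.3f, median %s, SE(mean) %s months\n",
              x$mean_os_months, format(x$median_os_months),
              format(x$se_mean_os_months)))
  cat(sprintf("  PFS: mean %.3f, median %s, SE(mean) %s months\n",
              x$mean_pfs_months, format(x$median_pfs_months),
              format(x$se_mean_pfs_months)))
  invisible(x)
}

#' Two-arm trial container
#'
#' Pairs the control-arm and intervention-arm [survival_summary()] objects.
#' Defaults are not supplied here; use [default_trial()] for the base-case
#' arm summaries (control n = 30, intervention n = 32).
#'
#' @param control,intervention `survival_summary` objects.
#' @return Object of class `two_arm_trial`.
#' @export
two_arm_trial <- function(control, intervention) {
  stopifnot(inherits(control, "survival_summary"),
            inherits(intervention, "survival_summary"))
  structure(list(control = control, intervention = intervention),
            class = "two_arm_trial")
}

#' @export
print.two_arm_trial <- function(x, ...) {
  cat("Two-arm trial\n-- control --\n")
  print(x$control)
  cat("-- intervention --\n")
  print(x$intervention)
  invisible(x)
}

#' Base-case two-arm trial summaries
#'
#' The published arm-level statistics of the phase II trial the model is
#' calibrated to: control arm (cisplatin/5-FU, n = 30) mean OS 8.6, mean PFS
#' 5.6, median OS 5.5, median PFS 3.6 months; intervention arm (plus
#' cetuximab, n = 32) mean OS 10.8, mean PFS 7.1, median OS 9.5, median PFS
#' 5.9 months. Standard errors are not published; supply them from a
#' synthetic cohort (see [generate_cohort()]) when running the PSA.
#'
#' @return A `two_arm_trial` object without standard errors.
#' @export
default_trial <- function() {
  two_arm_trial(
    control = survival_summary(
      n = 30, mean_os_months = 8.6, mean_pfs_months = 5.6,
      median_os_months = 5.5, median_pfs_months = 3.6),
    intervention = survival_summary(
      n = 32, mean_os_months = 10.8, mean_pfs_months = 7.1,
      median_os_months = 9.5, median_pfs_months = 5.9))
}

#' Summarize a patient-level cohort into arm-level statistics
#'
#' Computes, for one arm of a patient record table, the arithmetic means,
#' sample medians (mean of the two central order statistics for even n) and
#' standard errors of the means (sample SD with the n - 1 denominator divided
#' by sqrt(n)) of OS and PFS.
#'
#' @param records Patient record table (see [patient_records()]).
#' @param arm_label `"control"` or `"intervention"`.
#' @return A [survival_summary()] for the requested arm.
#' @export
summarize_cohort <- function(records, arm_label = c("control", "intervention")) {
  arm_label <- match.arg(arm_label)
  records <- patient_records(records)
  sub <- records[records$arm == arm_label, , drop = FALSE]
  n <- nrow(sub)
  if (n < 2) {
    stop(sprintf("arm '%s' has %d record(s); at least 2 are required to summarize",
                 arm_label, n), call. = FALSE)
  }
  survival_summary(
    n = n,
    mean_os_months = mean(sub$os_months),
    mean_pfs_months = mean(sub$pfs_months),
    median_os_months = stats::median(sub$os_months),
    median_pfs_months = stats::median(sub$pfs_months),
    se_mean_os_months = stats::sd(sub$os_months) / sqrt(n),
    se_mean_pfs_months = stats::sd(sub$pfs_months) / sqrt(n))
}

#' Consistency findings for a two-arm trial
#'
#' Returns human-readable findings instead of raising errors: PFS exceeding
#' OS, non-positive arm sizes, and missing standard errors when a PSA is
#' intended. An empty character vector means the trial is consistent.
#'
#' @param trial A `two_arm_trial`.
#' @param psa_requested Set `TRUE` to additionally require standard errors on
#'   all four means.
#' @return Character vector of findings (possibly empty).
#' @export
validate_trial <- function(trial, psa_requested = FALSE) {
  stopifnot(inherits(trial, "two_arm_trial"))
  findings <- character(0)
  for (arm in ARM_LEVELS) {
    s <- trial[[arm]]
    if (s$n < 1) {
      findings <- c(findings, sprintf("%s arm: non-positive n (%d)", arm, s$n))
    }
    if (s$mean_pfs_months > s$mean_os_months) {
      findings <- c(findings,
                    sprintf("%s arm: mean PFS exceeds mean OS (%.3f > %.3f months)",
                            arm, s$mean_pfs_months, s$mean_os_months))
    }
    if (psa_requested &&
        (is.na(s$se_mean_os_months) || is.na(s$se_mean_pfs_months))) {
      findings <- c(findings,
                    sprintf("%s arm: standard errors required for PSA are missing", arm))
    }
  }
  findings
}

#' Read a patient-level CSV table
#'
#' Expects a comma-separated UTF-8 file with a header row and columns `arm`,
#' `pfs_months`, `os_months` (dot decimal separator). The table is validated
#' on read.
#'
#' @param path Path to the CSV file.
#' @return A validated `patient_records` data frame.
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) stop("patient table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  patient_records(df)
}

#' Write a patient-level CSV table
#'
#' @param records Patient record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(records, path) {
  records <- patient_records(records)
  utils::write.csv(records[, c("arm", "pfs_months", "os_months")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a survival summary as JSON
#'
#' @param summary A `survival_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "survival_summary"))
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
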