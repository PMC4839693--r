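# Partitioned-survival utility model.
#
# Quality of life is 0.675 (symptomatic esophageal carcinoma) throughout
# progression-free survival and then declines linearly to 0 at death, so the
# average utility of the post-progression phase is the midpoint of 0.675 and
# 0. Effects are converted from months to years here and nowhere else.

#' Health-state utility weights
#'
#' @param u_pfs Utility during progression-free survival, in \[0, 1\]. The
#'   default 0.675 is the published weight for symptomatic esophageal
#'   carcinoma; 0.77 (asymptomatic disease) is kept available as an
#'   alternative scenario constant.
#' @param u_death Utility at death; fixed at 0.
#' @param u_asymptomatic_alt Alternative PFS weight for scenario analyses.
#' @return Object of class `health_state_utilities`.
#' @export
health_state_utilities <- function(u_pfs = 0.675, u_death = 0,
                                   u_asymptomatic_alt = 0.77) {
  if (!is.finite(u_pfs) || u_pfs < 0 || u_pfs > 1) {
    stop("u_pfs must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(as.numeric(u_death), 0)) {
    stop("u_death is fixed at 0 in this model", call. = FALSE)
  }
  if (!is.finite(u_asymptomatic_alt) || u_asymptomatic_alt < 0 || u_asymptomatic_alt > 1) {
    stop("u_asymptomatic_alt must lie in [0, 1]", call. = FALSE)
  }
  structure(list(u_pfs = u_pfs, u_death = 0,
                 u_asymptomatic_alt = u_asymptomatic_alt),
            class = "health_state_utilities")
}

#' Mean utility of the progressive-disease phase
#'
#' With utility declining linearly from `u_pfs` at progression to 0 at death,
#' the time-averaged utility of the progression phase is the midpoint
#' `(u_pfs + u_death) / 2` (0.3375 at the default weights).
#'
#' @param u A [health_state_utilities()] object.
#' @return Scalar utility weight.
#' @export
progression_utility <- function(u = health_state_utilities()) {
  stopifnot(inherits(u, "health_state_utilities"))
  (u$u_pfs + u$u_death) / 2
}

#' Life-years and QALYs for one arm
#'
#' Life-years are mean OS converted to years. QALYs weight the
#' progression-free phase by `u_pfs` and the post-progression phase
#' (mean OS minus mean PFS) by [progression_utility()]:
#' `(PFS/12) * u_pfs + ((OS - PFS)/12) * (u_pfs + 0)/2`.
#'
#' @param s A [survival_summary()].
#' @param u A [health_state_utilities()].
#' @return Object of class `effect_result` with fields `life_years` and
#'   `qalys` (both in years; `qalys <= life_years` since utilities are at
#'   most 1).
#' @export
arm_effects <- function(s, u = health_state_utilities()) {
  stopifnot(inherits(s, "survival_summary"),
            inherits(u, "health_state_utilities"))
  if (s$mean_pfs_months > s$mean_os_months) {
    stop("mean PFS exceeds mean OS", call. = FALSE)
  }
  ly <- s$mean_os_months / 12
  q <- (s$mean_pfs_months / 12) * u$u_pfs +
    ((s$mean_os_months - s$mean_pfs_months) / 12) * progression_utility(u)
  structure(list(life_years = ly, qalys = q), class = "effect_result")
}

#' @export
print.effect_result <- function(x, ...) {
  cat(sprintf("Effects: %.4f life-years, %.4f QALYs\n", x$life_years, x$qalys))
  invisible(x)
}

#' Incremental effects of the intervention arm over the control arm
#'
#' Component-wise intervention minus control; either difference may be
#' negative.
#'
#' @param trial A [two_arm_trial()].
#' @param u A [health_state_utilities()].
#' @return `effect_result` of differences (`life_years` = delta LY,
#'   `qalys` = delta QALY).
#' @export
incremental_effects <- function(trial, u = health_state_utilities()) {
  stopifnot(inherits(trial, "two_arm_trial"))
  ctrl <- arm_effects(trial$control, u)
  intv <- arm_effects(trial$intervention, u)
  structure(list(life_years = intv$life_years - ctrl$life_years,
                 qalys = intv$qalys - ctrl$qalys),
            class = "effect_result")
}
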