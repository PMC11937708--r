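#' Trial definitions
#'
#' The package models two parallel open-label RCTs of an ePRO app run in the
#' same region: a breast-cancer trial during neoadjuvant chemotherapy
#' (`"B_RCT"`) and a prostate-cancer trial during radiotherapy (`"P_RCT"`).
#' Each trial carries the constants the costing and windowing logic needs:
#' the regional patient pool over which the one-time startup cost is
#' amortized, the follow-up window for health-care utilization, and the
#' number of weeks of app reporting after the last treatment.
#'
#' @param trial `"B_RCT"` or `"P_RCT"`.
#'
#' @return A list of class `trial_spec` with elements `id`,
#'   `startup_pool_n`, `followup_window_days` and `reporting_tail_weeks`.
#'
#' @details The follow-up window is the half-open interval
#'   `[0, followup_window_days)` in days from the first treatment day, with
#'   183 days taken as "6 months".
#'
#' @examples
#' trial_spec("B_RCT")$startup_pool_n # 518
#' trial_spec("P_RCT")$startup_pool_n # 683
#' @export
trial_spec <- function(trial = c("B_RCT", "P_RCT")) {
  trial <- match.arg(trial)
  out <- switch(trial,
    B_RCT = list(
      id = "B_RCT",
      startup_pool_n = 518L,
      followup_window_days = 183L,
      reporting_tail_weeks = 2L
    ),
    P_RCT = list(
      id = "P_RCT",
      startup_pool_n = 683L,
      followup_window_days = 183L,
      reporting_tail_weeks = 3L
    )
  )
  structure(out, class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat("<trial_spec> ", x$id,
    ": startup pool n=", x$startup_pool_n,
    ", follow-up window ", x$followup_window_days, " days",
    ", reporting tail ", x$reporting_tail_weeks, " weeks\n",
    sep = ""
  )
  invisible(x)
}

trial_ids <- function() c("B_RCT", "P_RCT")
arm_levels <- function() c("intervention", "control")
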