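#' Screening policy configuration
#'
#' Bundles the temporal-context policy knobs used when reconstructing a
#' patient's state at an index prescription. All windows are in days; date
#' intervals throughout the package are half-open `[start, end)`.
#'
#' @param condition_lookback_days A coded reason for encounter counts as an
#'   active condition if recorded in `(index - lookback, index]`. Default 365.
#' @param chronic_icpc2_codes ICPC-2 rubrics treated as chronic: active from
#'   their first record onward, regardless of the lookback. The default covers
#'   dementia (P70), diabetes (T89/T90) and heart failure (K77).
#' @param egfr_staleness_days An eGFR value is current if measured in
#'   `(index - staleness, index]`. Default 365.
#' @param grace_gap_days Maximum gap between the end of one package's
#'   coverage and the next same-substance prescription for the two to count
#'   as one continuous course. Default 14.
#' @param default_coverage_days Assumed days of supply when a prescription
#'   has no (or an unknown) GTIN. Default 30, the modal one-month package.
#' @param bp_mode `"latest"` (default): blood pressure is elevated iff the
#'   most recent reading on or before the index date is elevated.
#'   `"any_within_window"`: elevated iff any reading within
#'   `bp_window_days` before the index is elevated.
#' @param bp_window_days Window used by `bp_mode = "any_within_window"`.
#' @param min_age_years Minimum age (completed years) at the prescription
#'   date for a prescription to be an index prescription. Default 65.
#' @param age_cutoffs Age cutoffs for stratified prevalence. Default 65/70/75.
#' @return A list of class `pim_config`.
#' @export
pim_config <- function(condition_lookback_days = 365,
                       chronic_icpc2_codes = c("P70", "T89", "T90", "K77"),
                       egfr_staleness_days = 365,
                       grace_gap_days = 14,
                       default_coverage_days = 30,
                       bp_mode = c("latest", "any_within_window"),
                       bp_window_days = 365,
                       min_age_years = 65,
                       age_cutoffs = c(65, 70, 75)) {
  bp_mode <- match.arg(bp_mode)
  stopifnot(
    condition_lookback_days > 0, egfr_staleness_days > 0,
    grace_gap_days >= 0, default_coverage_days >= 1,
    min_age_years >= 0, bp_window_days > 0
  )
  structure(
    list(
      condition_lookback_days = as.integer(condition_lookback_days),
      chronic_icpc2_codes = as.character(chronic_icpc2_codes),
      egfr_staleness_days = as.integer(egfr_staleness_days),
      grace_gap_days = as.integer(grace_gap_days),
      default_coverage_days = as.integer(default_coverage_days),
      bp_mode = bp_mode,
      bp_window_days = as.integer(bp_window_days),
      min_age_years = as.integer(min_age_years),
      age_cutoffs = as.integer(sort(age_cutoffs))
    ),
    class = "pim_config"
  )
}
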