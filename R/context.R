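## temporal_context: everything known about a patient at an index
## prescription — age, active comedication (package-size exposure windows),
## active conditions, latest eGFR, elevated-BP flag, and continuous-use
## duration of the index substance.
##
## Conventions (see the methods vignette):
##  * a prescription's coverage interval is half-open
##    [date, date + coverage_days);
##  * a condition is active if recorded in (index - lookback, index];
##    chronic-flagged rubrics are active from their first record onward;
##  * eGFR is current if measured in (index - staleness, index]; among
##    same-day labs the lowest value wins (conservative);
##  * BP uses the most recent reading on or before the index; among same-day
##    readings the one with the highest systolic (then diastolic) wins;
##  * missing data never satisfy a rule condition.

#' Medications active at a date
#'
#' ATC codes of all prescriptions whose coverage interval
#' `[date, date + coverage_days)` contains the query date.
#'
#' @param prescriptions one patient's prescriptions (`date`, `atc`, `gtin`,
#'   optionally `rid`).
#' @param date query date.
#' @param products validated product table.
#' @param default_coverage_days coverage for unknown GTINs.
#' @param exclude_rid optional `rid` of the index prescription itself, which
#'   is excluded for comedication tests.
#' @return sorted character vector of ATC codes.
#' @export
active_medications <- function(prescriptions, date, products,
                               default_coverage_days = 30,
                               exclude_rid = NULL) {
  rx <- as.data.frame(prescriptions)
  if (!nrow(rx)) return(character())
  if (!is.null(exclude_rid) && "rid" %in% names(rx)) {
    rx <- rx[!rx$rid %in% exclude_rid, , drop = FALSE]
  }
  date <- as.Date(date)
  cov <- coverage_days(rx$gtin, products, default_coverage_days)
  act <- rx$date <= date & date < rx$date + cov
  sort(unique(rx$atc[act]))
}

#' Conditions active at a date
#'
#' ICPC-2 codes recorded within the lookback window `(date - lookback, date]`.
#' Chronic-flagged codes are active from their first record onward.
#'
#' @param conditions one patient's condition records (`date`, `icpc2`).
#' @param date query date.
#' @param condition_lookback_days lookback window length in days.
#' @param chronic_icpc2_codes rubrics with the chronic override.
#' @return sorted character vector of ICPC-2 codes.
#' @export
active_conditions <- function(conditions, date,
                              condition_lookback_days = 365,
                              chronic_icpc2_codes = character()) {
  cc <- as.data.frame(conditions)
  if (!nrow(cc)) return(character())
  date <- as.Date(date)
  chronic <- cc$icpc2 %in% chronic_icpc2_codes
  act <- cc$date <= date &
    (chronic | cc$date > date - condition_lookback_days)
  sort(unique(cc$icpc2[act]))
}

#' Current eGFR at a date
#'
#' Most recent eGFR measured in `(date - staleness, date]`; `NA` when none
#' exists. Among same-day labs the lowest value is used.
#'
#' @param labs one patient's lab results (`date`, `egfr`).
#' @param date query date.
#' @param egfr_staleness_days staleness window in days.
#' @return numeric scalar or `NA`.
#' @export
current_egfr <- function(labs, date, egfr_staleness_days = 365) {
  ll <- as.data.frame(labs)
  date <- as.Date(date)
  ll <- ll[ll$date <= date & ll$date > date - egfr_staleness_days, , drop = FALSE]
  if (!nrow(ll)) return(NA_real_)
  ll <- ll[ll$date == max(ll$date), , drop = FALSE]
  min(ll$egfr)
}

#' Elevated blood pressure at a date
#'
#' With `mode = "latest"` (default): `TRUE` iff the most recent reading on or
#' before the date has systolic > 140 mm Hg or diastolic > 90 mm Hg (strict
#' inequalities). With `mode = "any_within_window"`: `TRUE` iff any reading
#' in `(date - window, date]` is elevated. `FALSE` when no reading exists.
#'
#' @param bp one patient's BP readings (`date`, `systolic`, `diastolic`).
#' @param date query date.
#' @param mode `"latest"` or `"any_within_window"`.
#' @param window_days window for `"any_within_window"`.
#' @return logical scalar.
#' @export
bp_elevated <- function(bp, date, mode = c("latest", "any_within_window"),
                        window_days = 365) {
  mode <- match.arg(mode)
  bb <- as.data.frame(bp)
  date <- as.Date(date)
  bb <- bb[bb$date <= date, , drop = FALSE]
  if (mode == "any_within_window") {
    bb <- bb[bb$date > date - window_days, , drop = FALSE]
    if (!nrow(bb)) return(FALSE)
    return(any(bb$systolic > 140 | bb$diastolic > 90))
  }
  if (!nrow(bb)) return(FALSE)
  bb <- bb[bb$date == max(bb$date), , drop = FALSE]
  bb <- bb[order(bb$systolic, bb$diastolic), , drop = FALSE]
  last <- bb[nrow(bb), ]
  last$systolic > 140 || last$diastolic > 90
}

#' Continuous-use chain of the index substance
#'
#' Same-ATC prescriptions are merged into continuous courses: a prescription
#' extends the current course if its date is at most `grace_gap_days` after
#' the running end of coverage (the maximum of `date + coverage_days` over
#' the course so far). `cumulative_use_days` is the summed coverage of all
#' course members up to and including the index date; `prior_same_atc_count`
#' counts course members strictly before the index date.
#'
#' @param same_atc_rx the patient's prescriptions of the index ATC (`date`,
#'   `gtin`), including the index itself.
#' @param index_date index prescription date.
#' @param products validated product table.
#' @param grace_gap_days allowed gap between coverage end and next fill.
#' @param default_coverage_days coverage for unknown GTINs.
#' @return list with `cumulative_use_days` and `prior_same_atc_count`.
#' @export
use_chain <- function(same_atc_rx, index_date, products,
                      grace_gap_days = 14, default_coverage_days = 30) {
  rx <- as.data.frame(same_atc_rx)
  rx <- rx[rx$date <= index_date, , drop = FALSE]
  rx <- rx[order(rx$date), , drop = FALSE]
  if (!nrow(rx)) return(list(cumulative_use_days = 0L, prior_same_atc_count = 0L))
  cov <- coverage_days(rx$gtin, products, default_coverage_days)
  d <- as.numeric(rx$date)
  seg_start <- 1L
  seg_end <- -Inf
  for (i in seq_along(d)) {
    if (d[i] > seg_end + grace_gap_days) seg_start <- i
    seg_end <- max(seg_end, d[i] + cov[i])
  }
  in_seg <- seq_along(d) >= seg_start
  list(
    cumulative_use_days = as.integer(sum(cov[in_seg])),
    prior_same_atc_count = as.integer(sum(in_seg & d < as.numeric(as.Date(index_date))))
  )
}

#' Build the evaluation context for one index prescription
#'
#' Assembles the patient's full state at the index date. `active_atc`
#' excludes the index prescription row itself (comedication semantics), but
#' other prescriptions of the same substance still count.
#'
#' @param index one row of [select_index_prescriptions()] output (needs
#'   `patient_id`, `date`, `atc`, `gtin`, `rid`).
#' @param cohort a `pim_cohort`.
#' @param products validated product table.
#' @param config a [pim_config()].
#' @return list of class `pim_context` with fields `patient_id`, `date`,
#'   `atc`, `gtin`, `rid`, `age_years`, `active_atc`, `active_icpc2`,
#'   `egfr`, `bp_elevated`, `daily_dose_mg`, `cumulative_use_days`,
#'   `prior_same_atc_count`.
#' @export
build_context <- function(index, cohort, products, config = pim_config()) {
  index <- as.list(index)
  pid <- index$patient_id
  d <- as.Date(index$date)
  prx <- as.data.frame(cohort$prescriptions[patient_id == pid])
  chain <- use_chain(prx[prx$atc == index$atc, , drop = FALSE], d, products,
                     config$grace_gap_days, config$default_coverage_days)
  birth <- cohort$patients[patient_id == pid, birth_date]
  structure(list(
    patient_id = pid, date = d, atc = index$atc, gtin = index$gtin,
    rid = index$rid,
    age_years = age_completed_years(birth, d),
    active_atc = active_medications(prx, d, products,
                                    config$default_coverage_days,
                                    exclude_rid = index$rid),
    active_icpc2 = active_conditions(
      as.data.frame(cohort$conditions[patient_id == pid]), d,
      config$condition_lookback_days, config$chronic_icpc2_codes
    ),
    egfr = current_egfr(as.data.frame(cohort$labs[patient_id == pid]), d,
                        config$egfr_staleness_days),
    bp_elevated = bp_elevated(as.data.frame(cohort$bp[patient_id == pid]), d,
                              config$bp_mode, config$bp_window_days),
    daily_dose_mg = unname(daily_dose_mg(index$gtin, products)),
    cumulative_use_days = chain$cumulative_use_days,
    prior_same_atc_count = chain$prior_same_atc_count
  ), class = "pim_context")
}

## Vectorized context construction for all index prescriptions at once.
## Same semantics as build_context(); used by flag_prescriptions() so that
## cohorts with tens of thousands of prescriptions evaluate in seconds.
build_contexts <- function(cohort, idx, products, config = pim_config()) {
  idx <- data.table::as.data.table(idx)
  if (!nrow(idx)) {
    return(data.table::data.table(
      patient_id = character(), date = as.Date(character()),
      atc = character(), gtin = character(), rid = integer(),
      age_years = integer(), daily_dose_mg = numeric(), egfr = numeric(),
      bp_elevated = logical(), cumulative_use_days = integer(),
      prior_same_atc_count = integer(), active_atc = list(),
      active_icpc2 = list()
    ))
  }
  ctx <- data.table::copy(idx)
  ctx[, daily_dose_mg := daily_dose_mg(gtin, products)]

  ## --- continuous-use chains per (patient, atc) --------------------------
  rx <- data.table::copy(cohort$prescriptions)
  rx[, coverage := coverage_days(gtin, products, config$default_coverage_days)]
  data.table::setorder(rx, patient_id, atc, date, rid)
  grace <- config$grace_gap_days
  rx[, `:=`(dnum = as.numeric(date), end = as.numeric(date) + coverage)]
  # A row starts a new course when its date exceeds the running maximum
  # coverage end of earlier same-substance rows by more than the grace gap.
  # (After a break the pre-break running max can never re-join: it is at
  # least grace + 1 days before the break date, hence before all later
  # dates too, so a plain cummax is sound.)
  rx[, prev_end := data.table::shift(cummax(end), 1, fill = -Inf),
     by = .(patient_id, atc)]
  rx[, seg_id := cumsum(dnum > prev_end + grace), by = .(patient_id, atc)]
  rx[, cum := cumsum(coverage), by = .(patient_id, atc, seg_id)]
  # order-free within a day: every row of a date carries the through-date total
  rx[, cum_days := max(cum), by = .(patient_id, atc, seg_id, date)]
  rx[, prior_n := match(dnum, dnum) - 1L, by = .(patient_id, atc, seg_id)]
  ctx <- merge(ctx, rx[, .(rid, cum_days, prior_n)], by = "rid", all.x = TRUE)
  data.table::setnames(ctx, c("cum_days", "prior_n"),
                       c("cumulative_use_days", "prior_same_atc_count"))

  ## --- latest eGFR within the staleness window ---------------------------
  labs <- cohort$labs[, .(egfr = min(egfr)), by = .(patient_id, date)]
  if (nrow(labs)) {
    pairs <- merge(ctx[, .(rid, patient_id, idx_date = date)], labs,
                   by = "patient_id", allow.cartesian = TRUE)
    pairs <- pairs[date <= idx_date &
                     date > idx_date - config$egfr_staleness_days]
    if (nrow(pairs)) {
      data.table::setorder(pairs, rid, date)
      latest <- pairs[, .SD[.N], by = rid]
      ctx <- merge(ctx, latest[, .(rid, egfr)], by = "rid", all.x = TRUE)
    }
  }
  if (!"egfr" %in% names(ctx)) ctx[, egfr := NA_real_]

  ## --- elevated BP --------------------------------------------------------
  bp <- data.table::copy(cohort$bp)
  if (nrow(bp)) {
    if (config$bp_mode == "latest") {
      # same-day tie: highest systolic, then diastolic
      data.table::setorder(bp, patient_id, date, systolic, diastolic)
      bp <- bp[, .SD[.N], by = .(patient_id, date)]
      pairs <- merge(ctx[, .(rid, patient_id, idx_date = date)], bp,
                     by = "patient_id", allow.cartesian = TRUE)
      pairs <- pairs[date <= idx_date]
      if (nrow(pairs)) {
        data.table::setorder(pairs, rid, date)
        latest <- pairs[, .SD[.N], by = rid]
        latest[, bp_elevated := systolic > 140 | diastolic > 90]
        ctx <- merge(ctx, latest[, .(rid, bp_elevated)], by = "rid", all.x = TRUE)
      }
    } else {
      pairs <- merge(ctx[, .(rid, patient_id, idx_date = date)], bp,
                     by = "patient_id", allow.cartesian = TRUE)
      pairs <- pairs[date <= idx_date & date > idx_date - config$bp_window_days]
      if (nrow(pairs)) {
        agg <- pairs[, .(bp_elevated = any(systolic > 140 | diastolic > 90)),
                     by = rid]
        ctx <- merge(ctx, agg, by = "rid", all.x = TRUE)
      }
    }
  }
  if (!"bp_elevated" %in% names(ctx)) ctx[, bp_elevated := NA]
  ctx[is.na(bp_elevated), bp_elevated := FALSE]

  ## --- active conditions --------------------------------------------------
  ctx[, active_icpc2 := vector("list", .N)]
  cc <- cohort$conditions
  if (nrow(cc)) {
    cc <- data.table::copy(cc)
    cc[, chronic := icpc2 %in% config$chronic_icpc2_codes]
    pairs <- merge(ctx[, .(rid, patient_id, idx_date = date)], cc,
                   by = "patient_id", allow.cartesian = TRUE)
    pairs <- pairs[date <= idx_date &
                     (chronic | date > idx_date - config$condition_lookback_days)]
    if (nrow(pairs)) {
      agg <- pairs[, .(codes = list(sort(unique(icpc2)))), by = rid]
      ctx[match(agg$rid, rid), active_icpc2 := agg$codes]
    }
  }
  ctx[, active_icpc2 := lapply(active_icpc2, function(x) x %||% character())]

  ## --- active comedication (excluding the index row itself) ---------------
  ctx[, active_atc := vector("list", .N)]
  pairs <- merge(ctx[, .(rid, patient_id, idx_date = date)],
                 rx[, .(patient_id, date, atc, rid2 = rid, end)],
                 by = "patient_id", allow.cartesian = TRUE)
  pairs <- pairs[date <= idx_date & as.numeric(idx_date) < end & rid2 != rid]
  if (nrow(pairs)) {
    agg <- pairs[, .(codes = list(sort(unique(atc)))), by = rid]
    ctx[match(agg$rid, rid), active_atc := agg$codes]
  }
  ctx[, active_atc := lapply(active_atc, function(x) x %||% character())]

  data.table::setorder(ctx, patient_id, date, atc, gtin, na.last = TRUE)
  ctx[, .(patient_id, date, atc, gtin, rid, age_years, daily_dose_mg, egfr,
          bp_elevated, cumulative_use_days, prior_same_atc_count,
          active_atc, active_icpc2)]
}
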