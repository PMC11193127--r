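## pim_metrics: the statistics computed on a flag table — age-stratified
## period prevalence, PIM frequency, per-patient burden, top-N substance
## rankings, therapeutic-class distribution, and list-overlap counts.
##
## Conventions: the reporting dimension is the six list ids plus "combined".
## Age-subset membership uses the patient's age at their *first* index
## prescription (patients crossing a cutoff mid-period belong to the higher
## stratum only from the perspective of later prescriptions, which is why a
## list's numerator can be identical at cutoffs below its age gate while
## denominators shrink). Percentages are stored unrounded; round at output.

METRIC_LISTS <- c(PIM_LIST_IDS, "combined")

# patient-level summary: first-index age and per-list any-PIM indicators
patient_flag_summary <- function(flags) {
  stopifnot(inherits(flags, "pim_flags"))
  dt <- data.table::as.data.table(flags)
  data.table::setorder(dt, patient_id, date, atc)
  dt[, {
    first <- .SD[1]
    c(list(first_age = first$age_years, n_rx = .N),
      lapply(.SD[, METRIC_LISTS, with = FALSE], any),
      lapply(setNames(METRIC_LISTS, paste0("n_", METRIC_LISTS)),
             function(l) sum(.SD[[l]])))
  }, by = patient_id]
}

#' Age-stratified PIM period prevalence
#'
#' For each list (and the combined list) and each age cutoff `A`: the
#' denominator is the number of patients whose age at their first index
#' prescription is at least `A`; the numerator is the subset of those with
#' at least one flagged prescription. Prevalence is `100 * numerator /
#' denominator` (`NA` when the denominator is empty).
#'
#' @param flags a `pim_flags` table ([flag_prescriptions()]).
#' @param age_cutoffs integer vector of cutoffs; default 65/70/75.
#' @return data.table: `list_id`, `age_cutoff`, `n_patients`, `n_with_pim`,
#'   `prevalence_pct`.
#' @export
pim_prevalence <- function(flags, age_cutoffs = c(65, 70, 75)) {
  ps <- patient_flag_summary(flags)
  out <- data.table::CJ(list_id = METRIC_LISTS, age_cutoff = sort(age_cutoffs),
                        sorted = FALSE)
  out[, c("n_patients", "n_with_pim") := {
    sub <- ps[first_age >= age_cutoff]
    .(nrow(sub), sum(sub[[list_id]]))
  }, by = .(list_id, age_cutoff)]
  out[, prevalence_pct := ifelse(n_patients > 0, 100 * n_with_pim / n_patients,
                                 NA_real_)]
  out[]
}

#' PIM frequency
#'
#' Percentage of all index prescriptions flagged, per list and combined.
#'
#' @param flags a `pim_flags` table.
#' @return data.table: `list_id`, `n_prescriptions`, `n_pim`,
#'   `frequency_pct` (`NA` when there are no prescriptions).
#' @export
pim_frequency <- function(flags) {
  stopifnot(inherits(flags, "pim_flags"))
  n <- nrow(flags)
  data.table::data.table(
    list_id = METRIC_LISTS,
    n_prescriptions = n,
    n_pim = vapply(METRIC_LISTS, function(l) sum(flags[[l]]), integer(1)),
    frequency_pct = vapply(METRIC_LISTS, function(l) {
      if (n > 0) 100 * sum(flags[[l]]) / n else NA_real_
    }, numeric(1))
  )
}

#' Per-patient PIM burden
#'
#' For every included patient (all patients with at least one index
#' prescription, zero-PIM patients included): the number of flagged
#' prescriptions, and the percentage of the patient's own prescriptions
#' that are flagged. Reported as mean and population SD (divisor `n`)
#' across patients, per list and combined.
#'
#' @param flags a `pim_flags` table.
#' @return data.table: `list_id`, `n_patients`, `mean_pims_per_patient`,
#'   `sd_pims_per_patient`, `mean_pct_of_prescriptions`,
#'   `sd_pct_of_prescriptions`.
#' @export
pim_burden <- function(flags) {
  ps <- patient_flag_summary(flags)
  pop_sd <- function(x) if (length(x)) sqrt(mean((x - mean(x))^2)) else NA_real_
  data.table::rbindlist(lapply(METRIC_LISTS, function(l) {
    cnt <- ps[[paste0("n_", l)]]
    pct <- 100 * cnt / ps$n_rx
    data.table::data.table(
      list_id = l, n_patients = nrow(ps),
      mean_pims_per_patient = if (nrow(ps)) mean(cnt) else NA_real_,
      sd_pims_per_patient = pop_sd(cnt),
      mean_pct_of_prescriptions = if (nrow(ps)) mean(pct) else NA_real_,
      sd_pct_of_prescriptions = pop_sd(pct)
    )
  }))
}

#' Top-N most frequently prescribed PIMs
#'
#' Flagged prescriptions grouped by the index prescription's bottom-level
#' ATC code, per list and combined. Ranked by count descending, ties broken
#' by ATC code ascending. `pct_of_all_pims` is relative to that list's total
#' flagged prescriptions.
#'
#' @param flags a `pim_flags` table.
#' @param n ranking depth (default 10); shorter when fewer distinct
#'   substances are flagged.
#' @param labels optional named vector ATC -> substance label.
#' @return data.table: `list_id`, `rank`, `atc`, `substance_label`, `n_pim`,
#'   `pct_of_all_pims`.
#' @export
pim_top_n <- function(flags, n = 10, labels = atc_labels()) {
  stopifnot(inherits(flags, "pim_flags"))
  dt <- data.table::as.data.table(flags)
  data.table::rbindlist(lapply(METRIC_LISTS, function(l) {
    sub <- dt[dt[[l]] == TRUE]
    if (!nrow(sub)) return(NULL)
    total <- nrow(sub)
    counts <- sub[, .(n_pim = .N), by = atc]
    data.table::setorder(counts, -n_pim, atc)
    top <- head(counts, n)
    data.table::data.table(
      list_id = l, rank = seq_len(nrow(top)), atc = top$atc,
      substance_label = ifelse(is.na(labels[top$atc]), top$atc,
                               labels[top$atc]),
      n_pim = top$n_pim,
      pct_of_all_pims = 100 * top$n_pim / total
    )
  }))
}

#' Distribution of PIM prescriptions across therapeutic drug classes
#'
#' Every combined-flagged prescription is assigned to exactly one
#' therapeutic class of `map` (or `"other"`). Reports counts, percentage of
#' all combined-list PIM prescriptions, and — with classes sorted by
#' descending share — the cumulative share of the top-k classes.
#'
#' @param flags a `pim_flags` table.
#' @param map a [therapeutic_class_map()].
#' @return data.table: `class_label`, `n_pim`, `pct_of_all_pims`,
#'   `cumulative_pct` (classes with zero PIMs included).
#' @export
pim_class_distribution <- function(flags, map = therapeutic_class_map()) {
  stopifnot(inherits(flags, "pim_flags"))
  sub <- flags[flags$combined == TRUE]
  total <- nrow(sub)
  all_labels <- c(unique(map$class_label), "other")
  cls <- classify_atc(sub$atc, map)
  counts <- table(factor(cls, levels = all_labels))
  out <- data.table::data.table(
    class_label = names(counts),
    n_pim = as.integer(counts),
    pct_of_all_pims = if (total > 0) 100 * as.integer(counts) / total else 0
  )
  data.table::setorder(out, -n_pim, class_label)
  out[, cumulative_pct := cumsum(pct_of_all_pims)]
  out[]
}

#' List-overlap counts
#'
#' For every non-empty subset S of the six lists: the number of flagged
#' units (prescriptions, or patients with at least one flagged
#' prescription) flagged by exactly the lists in S. Subset counts sum to the
#' combined-flagged total.
#'
#' @param flags a `pim_flags` table.
#' @param unit `"prescription"` (default) or `"patient"`.
#' @return data.table: `subset` (list ids joined by `+`), `n_lists`, `n`.
#' @export
pim_overlap <- function(flags, unit = c("prescription", "patient")) {
  unit <- match.arg(unit)
  stopifnot(inherits(flags, "pim_flags"))
  if (unit == "prescription") {
    m <- as.matrix(as.data.frame(flags)[, PIM_LIST_IDS, drop = FALSE])
  } else {
    ps <- patient_flag_summary(flags)
    m <- as.matrix(as.data.frame(ps)[, PIM_LIST_IDS, drop = FALSE])
  }
  any_flag <- rowSums(m) > 0
  m <- m[any_flag, , drop = FALSE]
  if (!nrow(m)) {
    return(data.table::data.table(subset = character(), n_lists = integer(),
                                  n = integer()))
  }
  key <- apply(m, 1, function(r) paste(PIM_LIST_IDS[r], collapse = "+"))
  tab <- table(key)
  out <- data.table::data.table(
    subset = names(tab),
    n_lists = lengths(strsplit(names(tab), "+", fixed = TRUE)),
    n = as.integer(tab)
  )
  data.table::setorder(out, -n, subset)
  out[]
}
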