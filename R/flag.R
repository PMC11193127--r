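## criteria_engine: whole-cohort evaluation. One row per index prescription,
## one boolean verdict per PIM list, plus the combined (union) verdict and
## the matched rule ids.

#' Flag all index prescriptions against all PIM lists
#'
#' Selects the index prescriptions, reconstructs every prescription context,
#' and evaluates every rule of every list. The result has one row per index
#' prescription with six per-list verdicts, the combined verdict (`TRUE` iff
#' at least one list flags the prescription), and the set of matched rule
#' ids. The computation is a pure function of its inputs: identical inputs
#' give identical tables.
#'
#' @param cohort a `pim_cohort`.
#' @param rules a `pim_rules` object ([load_rule_file()]).
#' @param products validated product table ([pim_products()]).
#' @param config a [pim_config()].
#' @return data.table of class `pim_flags`, ordered by
#'   (patient_id, date, atc, gtin): columns `patient_id`, `date`, `atc`,
#'   `gtin`, `rid`, `age_years`, one logical column per list id, `combined`,
#'   and `matched_rules` (list-column of character vectors).
#' @export
flag_prescriptions <- function(cohort, rules, products,
                               config = pim_config()) {
  stopifnot(inherits(cohort, "pim_cohort"), inherits(rules, "pim_rules"))
  idx <- select_index_prescriptions(cohort, config$min_age_years)
  ctx <- build_contexts(cohort, idx, products, config)
  n <- nrow(ctx)

  verdicts <- matrix(FALSE, nrow = n, ncol = length(PIM_LIST_IDS),
                     dimnames = list(NULL, PIM_LIST_IDS))
  matched <- rep(list(character()), n)

  for (lid in PIM_LIST_IDS) {
    plist <- rules$lists[[lid]]
    gate <- ctx$age_years >= plist$target_min_age_years
    for (rule in plist$rules) {
      cand <- which(gate & ctx$atc %in% rule$trigger_atc)
      if (!length(cand)) next
      cond <- rule$conditions
      if (!is.null(cond$max_daily_dose_mg)) {
        dd <- ctx$daily_dose_mg[cand]
        cand <- cand[!is.na(dd) & dd > cond$max_daily_dose_mg]
      }
      if (length(cand) && !is.null(cond$min_cumulative_use_days)) {
        cand <- cand[ctx$cumulative_use_days[cand] > cond$min_cumulative_use_days]
      }
      if (length(cand) && !is.null(cond$required_icpc2_any)) {
        hit <- vapply(ctx$active_icpc2[cand],
                      function(x) any(cond$required_icpc2_any %in% x),
                      logical(1))
        cand <- cand[hit]
      }
      if (length(cand) && !is.null(cond$absent_icpc2_all)) {
        hit <- vapply(ctx$active_icpc2[cand],
                      function(x) any(cond$absent_icpc2_all %in% x),
                      logical(1))
        cand <- cand[!hit]
      }
      if (length(cand) && !is.null(cond$comedication_any)) {
        hit <- vapply(ctx$active_atc[cand],
                      function(x) any(rule$comedication_atc %in% x),
                      logical(1))
        cand <- cand[hit]
      }
      if (length(cand) && !is.null(cond$egfr_below)) {
        eg <- ctx$egfr[cand]
        cand <- cand[!is.na(eg) & eg < cond$egfr_below]
      }
      if (length(cand) && !is.null(cond$bp_elevated_required)) {
        cand <- cand[ctx$bp_elevated[cand]]
      }
      if (length(cand)) {
        verdicts[cand, lid] <- TRUE
        matched[cand] <- lapply(matched[cand], c, rule$rule_id)
      }
    }
  }

  flags <- ctx[, .(patient_id, date, atc, gtin, rid, age_years)]
  for (lid in PIM_LIST_IDS) flags[, (lid) := verdicts[, lid]]
  flags[, combined := Reduce(`|`, lapply(PIM_LIST_IDS, function(l) flags[[l]]))]
  if (!n) flags[, combined := logical()]
  flags[, matched_rules := matched]
  data.table::setattr(flags, "class", c("pim_flags", class(flags)))
  flags[]
}

#' Flatten a flag table for delimited-text output
#'
#' Collapses the `matched_rules` list-column to a `;`-separated string.
#'
#' @param flags a `pim_flags` table.
#' @return plain data.frame.
#' @export
flags_as_dataframe <- function(flags) {
  df <- as.data.frame(flags)
  df$matched_rules <- vapply(flags$matched_rules, paste, "", collapse = ";")
  df
}
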