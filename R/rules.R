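## criteria_engine: declarative PIM criteria. A rule names its trigger
## substances (ATC codes or class references) and a conjunction of condition
## clauses; a PIM list is a versioned collection of rules behind an age gate.

CONDITION_KEYS <- c(
  "max_daily_dose_mg",       # fires when daily dose >  threshold (strict)
  "min_cumulative_use_days", # fires when continuous use > threshold (strict)
  "required_icpc2_any",      # fires when any listed rubric is active
  "absent_icpc2_all",        # fires only when none of the rubrics is active
  "comedication_any",        # fires when any listed ATC/class is comedicated
  "egfr_below",              # fires when eGFR is known and < threshold
  "bp_elevated_required"     # fires when BP is elevated at the index date
)

# Age gates as published: Beers 2019 / PRISCUS / Mann / EU(7) target >=65,
# NORGEP >=70, Laroche >=75.
LIST_TARGET_AGE <- c(beers2019 = 65L, laroche = 75L, norgep = 70L,
                     priscus = 65L, mann = 65L, eu7 = 65L)

#' Load a machine-readable PIM rule file
#'
#' Parses and validates a YAML rule file: shared drug-class definitions plus
#' one rule collection per PIM list. All class references are resolved at
#' load time; any unknown list id, unresolved class reference, duplicate
#' rule id, unknown clause key or non-positive threshold is fatal with a
#' rule-level diagnostic.
#'
#' All six lists are always present in the result (with empty rule sets if
#' the file does not mention them), each carrying its published minimum
#' target age.
#'
#' @param path YAML file path. See `system.file("extdata", "rules_demo.yaml",
#'   package = "pimscreen")` for the documented schema.
#' @return Object of class `pim_rules`: list with `classes` (named list of
#'   ATC sets) and `lists` (named list of `PIMList`s, each with `list_id`,
#'   `target_min_age_years` and named `rules`). Every rule carries its
#'   expanded `trigger_atc` set and, where applicable, expanded
#'   `comedication_atc`.
#' @export
load_rule_file <- function(path) {
  if (!file.exists(path)) {
    pim_stop(paste("rule file not found:", path), "pim_io_error")
  }
  raw <- yaml::read_yaml(path)
  build_rules(raw)
}

# Build a pim_rules object from an already-parsed structure (list form of
# the YAML schema). Exposed internally so tests can construct rule sets in
# code.
build_rules <- function(raw) {
  classes <- lapply(raw$classes %||% list(), function(x) expand_class(unlist(x)))
  if (is.null(names(classes)) && length(classes)) {
    pim_stop("classes must be a named mapping class_id -> ATC codes",
             "pim_rule_error")
  }

  resolve <- function(entries, rule_id, what) {
    entries <- unlist(entries)
    if (!length(entries)) {
      pim_stop(sprintf("rule '%s': empty %s set", rule_id, what),
               "pim_rule_error")
    }
    out <- character()
    for (e in entries) {
      if (is_atc(e)) {
        out <- c(out, e)
      } else if (e %in% names(classes)) {
        out <- c(out, classes[[e]])
      } else {
        pim_stop(sprintf(
          "rule '%s': '%s' is neither a bottom-level ATC code nor a defined class",
          rule_id, e), "pim_rule_error")
      }
    }
    sort(unique(out))
  }

  lists_raw <- raw$lists %||% list()
  unknown <- setdiff(names(lists_raw), PIM_LIST_IDS)
  if (length(unknown)) {
    pim_stop(paste("unknown PIM list id(s):", paste(unknown, collapse = ", ")),
             "pim_rule_error")
  }

  seen_rule_ids <- character()
  lists <- lapply(PIM_LIST_IDS, function(lid) {
    spec <- lists_raw[[lid]] %||% list()
    target <- as.integer(spec$target_min_age_years %||% LIST_TARGET_AGE[[lid]])
    if (is.na(target) || target < 65L) {
      pim_stop(sprintf("list '%s': target_min_age_years must be >= 65", lid),
               "pim_rule_error")
    }
    rules <- lapply(spec$rules %||% list(), function(r) {
      rid <- r$rule_id %||% pim_stop("rule without rule_id", "pim_rule_error")
      if (rid %in% seen_rule_ids) {
        pim_stop(paste("duplicate rule_id:", rid), "pim_rule_error")
      }
      seen_rule_ids <<- c(seen_rule_ids, rid)
      conds <- r$conditions %||% list()
      bad <- setdiff(names(conds), CONDITION_KEYS)
      if (length(bad)) {
        pim_stop(sprintf("rule '%s': unknown condition clause(s): %s", rid,
                         paste(bad, collapse = ", ")), "pim_rule_error")
      }
      for (k in c("max_daily_dose_mg", "min_cumulative_use_days", "egfr_below")) {
        if (!is.null(conds[[k]]) &&
            (!is.numeric(conds[[k]]) || conds[[k]] <= 0)) {
          pim_stop(sprintf("rule '%s': %s threshold must be positive", rid, k),
                   "pim_rule_error")
        }
      }
      for (k in c("required_icpc2_any", "absent_icpc2_all")) {
        if (!is.null(conds[[k]])) {
          codes <- unlist(conds[[k]])
          if (!length(codes) || !all(is_icpc2(codes))) {
            pim_stop(sprintf("rule '%s': %s must list ICPC-2 rubrics", rid, k),
                     "pim_rule_error")
          }
          conds[[k]] <- as.character(codes)
        }
      }
      if (!is.null(conds$bp_elevated_required) &&
          !isTRUE(conds$bp_elevated_required)) {
        pim_stop(sprintf("rule '%s': bp_elevated_required must be true", rid),
                 "pim_rule_error")
      }
      comed <- NULL
      if (!is.null(conds$comedication_any)) {
        comed <- resolve(conds$comedication_any, rid, "comedication")
      }
      list(
        rule_id = rid,
        list_id = lid,
        trigger = unlist(r$trigger),
        trigger_atc = resolve(r$trigger, rid, "trigger"),
        conditions = conds,
        comedication_atc = comed,
        severity = r$severity %||% NA_character_,
        annotation = r$annotation %||% NA_character_
      )
    })
    names(rules) <- vapply(rules, `[[`, "", "rule_id")
    list(list_id = lid, target_min_age_years = target, rules = rules)
  })
  names(lists) <- PIM_LIST_IDS

  structure(list(version = raw$version %||% 1L, classes = classes,
                 lists = lists),
            class = "pim_rules")
}

#' Path to the shipped demo rule file
#'
#' An illustrative, machine-readable subset of criteria (~48 rules across
#' all six lists, covering every clause kind). It is **not** a clinically
#' complete transcription of any published list; thresholds are
#' illustrative.
#'
#' @return File path.
#' @export
demo_rules_path <- function() {
  system.file("extdata", "rules_demo.yaml", package = "pimscreen",
              mustWork = TRUE)
}

#' Evaluate one criteria rule against a prescription context
#'
#' `TRUE` iff the index substance is in the rule's expanded trigger set and
#' every condition clause is satisfied. An empty conjunction makes the rule
#' unconditional for its trigger substances. Clauses that need unavailable
#' data (daily dose without a known GTIN, eGFR without a current lab)
#' evaluate to `FALSE`: missing data never trigger.
#'
#' Dose and eGFR comparisons are strict (`>` threshold, `<` threshold).
#'
#' @param rule a rule from a `pim_rules` object.
#' @param ctx a [build_context()] result (or any list with the same fields).
#' @return logical scalar.
#' @export
evaluate_rule <- function(rule, ctx) {
  if (!ctx$atc %in% rule$trigger_atc) return(FALSE)
  cond <- rule$conditions
  if (!is.null(cond$max_daily_dose_mg)) {
    if (is.na(ctx$daily_dose_mg) ||
        ctx$daily_dose_mg <= cond$max_daily_dose_mg) return(FALSE)
  }
  if (!is.null(cond$min_cumulative_use_days)) {
    if (ctx$cumulative_use_days <= cond$min_cumulative_use_days) return(FALSE)
  }
  if (!is.null(cond$required_icpc2_any)) {
    if (!any(cond$required_icpc2_any %in% ctx$active_icpc2)) return(FALSE)
  }
  if (!is.null(cond$absent_icpc2_all)) {
    if (any(cond$absent_icpc2_all %in% ctx$active_icpc2)) return(FALSE)
  }
  if (!is.null(cond$comedication_any)) {
    if (!any(rule$comedication_atc %in% ctx$active_atc)) return(FALSE)
  }
  if (!is.null(cond$egfr_below)) {
    if (is.na(ctx$egfr) || ctx$egfr >= cond$egfr_below) return(FALSE)
  }
  if (!is.null(cond$bp_elevated_required)) {
    if (!isTRUE(ctx$bp_elevated)) return(FALSE)
  }
  TRUE
}

#' Evaluate one PIM list against a prescription context
#'
#' The list's age gate applies first: a prescription written below the
#' list's minimum target age is never flagged by that list, whatever its
#' rules say. Rules combine by OR; all matching rule ids are returned.
#'
#' @param pim_list one element of `pim_rules$lists`.
#' @param ctx a [build_context()] result.
#' @return list with `match` (logical) and `rule_ids` (character).
#' @export
evaluate_list <- function(pim_list, ctx) {
  if (ctx$age_years < pim_list$target_min_age_years) {
    return(list(match = FALSE, rule_ids = character()))
  }
  hits <- vapply(pim_list$rules, evaluate_rule, logical(1), ctx = ctx)
  list(match = any(hits), rule_ids = names(hits)[hits])
}

# Rules usable for rate-identification experiments: unconditional rules
# whose expanded trigger set does not intersect any other list's trigger
# expansion, so a planted prescription can only ever be flagged by its own
# list.
exclusive_unconditional_rules <- function(rules) {
  stopifnot(inherits(rules, "pim_rules"))
  all_triggers <- lapply(rules$lists, function(l) {
    sort(unique(unlist(lapply(l$rules, `[[`, "trigger_atc"))))
  })
  out <- list()
  for (lid in names(rules$lists)) {
    others <- unique(unlist(all_triggers[setdiff(names(all_triggers), lid)]))
    for (r in rules$lists[[lid]]$rules) {
      if (!length(r$conditions) && !any(r$trigger_atc %in% others)) {
        out[[r$rule_id]] <- r
      }
    }
  }
  out
}
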