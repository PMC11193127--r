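## drug_knowledge: named drug classes (enumerated ATC sets, as PIM list
## authors define them) and the coarser therapeutic-class map used for
## reporting the distribution of PIM prescriptions across drug classes.

#' Expand a drug class to its ATC code set
#'
#' Classes are enumerated sets of bottom-level ATC codes, mirroring
#' substance-level compilation of criteria lists; there is no prefix
#' wildcarding at rule level. Expansion deduplicates, is order-insensitive
#' and idempotent.
#'
#' @param atc_codes character vector of bottom-level ATC codes.
#' @return sorted unique character vector.
#' @export
expand_class <- function(atc_codes) {
  atc_codes <- unique(as.character(atc_codes))
  if (!length(atc_codes)) {
    pim_stop("drug class with empty member set", "pim_rule_error")
  }
  bad <- atc_codes[!is_atc(atc_codes)]
  if (length(bad)) {
    pim_stop(paste("class member(s) not bottom-level ATC codes:",
                   paste(bad, collapse = ", ")), "pim_rule_error")
  }
  sort(atc_codes)
}

#' Therapeutic-class map for reporting
#'
#' Maps bottom-level ATC codes to coarse therapeutic classes via ATC
#' prefixes (reporting only; criteria rules always use enumerated sets).
#' Prefixes must be pairwise non-nested so that every ATC code matches at
#' most one class; unmatched codes fall into `"other"`.
#'
#' @param map data.frame with columns `class_label`, `atc_or_prefix`. Default:
#'   the built-in map covering analgesics, proton pump inhibitors,
#'   benzodiazepines and benzodiazepine-like drugs, antidepressants,
#'   neuroleptics, antihypertensives, laxatives, antiepileptics, antidementia
#'   drugs and oral antidiabetics.
#' @return object of class `pim_class_map`.
#' @export
therapeutic_class_map <- function(map = default_therapeutic_classes()) {
  map <- as.data.frame(map)
  stopifnot(all(c("class_label", "atc_or_prefix") %in% names(map)))
  map$class_label <- as.character(map$class_label)
  map$atc_or_prefix <- toupper(as.character(map$atc_or_prefix))
  if ("other" %in% map$class_label) {
    pim_stop("'other' is reserved for unmapped codes", "pim_validation_error")
  }
  # pairwise disjointness: no prefix may be a prefix of another
  pref <- map$atc_or_prefix
  for (i in seq_along(pref)) {
    clash <- which(startsWith(pref, pref[i]) & seq_along(pref) != i)
    if (length(clash)) {
      pim_stop(sprintf(
        "therapeutic classes overlap: '%s' (%s) is a prefix of '%s' (%s)",
        pref[i], map$class_label[i], pref[clash[1]], map$class_label[clash[1]]
      ), "pim_validation_error")
    }
  }
  structure(map, class = c("pim_class_map", "data.frame"))
}

#' @rdname therapeutic_class_map
#' @export
default_therapeutic_classes <- function() {
  data.frame(
    class_label = c(
      "analgesics", "analgesics",
      "proton pump inhibitors",
      "benzodiazepines and benzodiazepine-like drugs",
      "benzodiazepines and benzodiazepine-like drugs",
      "benzodiazepines and benzodiazepine-like drugs",
      "antidepressants", "neuroleptics",
      "antihypertensives", "antihypertensives", "antihypertensives",
      "antihypertensives", "antihypertensives",
      "laxatives", "antiepileptics", "antidementia drugs",
      "oral antidiabetics"
    ),
    atc_or_prefix = c(
      "N02", "M01A",
      "A02BC",
      "N05BA", "N05CD", "N05CF",
      "N06A", "N05A",
      "C02", "C03", "C07", "C08", "C09",
      "A06A", "N03A", "N06D",
      "A10B"
    ),
    stringsAsFactors = FALSE
  )
}

#' Read a therapeutic-class map from CSV (`class_label,atc_or_prefix`)
#'
#' @param path CSV file path.
#' @return object of class `pim_class_map`.
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) {
    pim_stop(paste("class map file not found:", path), "pim_io_error")
  }
  therapeutic_class_map(utils::read.csv(path, colClasses = "character"))
}

#' Assign ATC codes to therapeutic classes
#'
#' Each code maps to exactly one class (the unique matching prefix) or to
#' `"other"`.
#'
#' @param atc character vector of bottom-level ATC codes.
#' @param map a `pim_class_map`.
#' @return character vector of class labels.
#' @export
classify_atc <- function(atc, map = therapeutic_class_map()) {
  stopifnot(inherits(map, "pim_class_map"))
  out <- rep("other", length(atc))
  for (i in seq_len(nrow(map))) {
    hit <- startsWith(as.character(atc), map$atc_or_prefix[i])
    out[hit] <- map$class_label[i]
  }
  out
}
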