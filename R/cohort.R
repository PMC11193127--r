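## ehr_data_model: domain types for the four EHR event streams plus
## demographics, with strict delimited-text readers/writers.
##
## Interchange format (UTF-8 CSV, ISO-8601 dates, fixed headers):
##   patients.csv      patient_id,sex,birth_date
##   prescriptions.csv patient_id,date,atc,gtin
##   conditions.csv    patient_id,date,icpc2
##   labs.csv          patient_id,date,egfr
##   bp.csv            patient_id,date,systolic,diastolic

COHORT_STREAMS <- list(
  patients      = c("patient_id", "sex", "birth_date"),
  prescriptions = c("patient_id", "date", "atc", "gtin"),
  conditions    = c("patient_id", "date", "icpc2"),
  labs          = c("patient_id", "date", "egfr"),
  bp            = c("patient_id", "date", "systolic", "diastolic")
)

#' Assemble and validate a cohort
#'
#' Bundles the five record streams into a validated cohort object. All type
#' and referential invariants are checked; any violation aborts with a
#' row-numbered diagnostic report (condition class
#' `pim_validation_error`, diagnostics in its `data` field).
#'
#' Events dated before `study_period[1]` are retained: pre-period history is
#' needed to reconstruct exposure windows and active conditions. Only the
#' selection of *index* prescriptions ([select_index_prescriptions()]) is
#' period-restricted.
#'
#' @param patients data.frame with columns `patient_id`, `sex`
#'   (`"female"`/`"male"`), `birth_date`.
#' @param prescriptions data.frame with `patient_id`, `date`, `atc`
#'   (7-character bottom-level ATC code), `gtin` (8-14 digits or `NA`).
#' @param conditions data.frame with `patient_id`, `date`, `icpc2`.
#' @param labs data.frame with `patient_id`, `date`, `egfr` (mL/min/1.73m2).
#' @param bp data.frame with `patient_id`, `date`, `systolic`, `diastolic`
#'   (mm Hg).
#' @param study_period length-2 `Date` vector; half-open `[start, end)`.
#' @return An object of class `pim_cohort`: a list of sorted data.tables
#'   (`patients`, `prescriptions`, `conditions`, `labs`, `bp`) plus
#'   `study_period`. Prescriptions carry a stable row id `rid`.
#' @export
pim_cohort <- function(patients, prescriptions, conditions, labs, bp,
                       study_period) {
  study_period <- as.Date(study_period)
  if (length(study_period) != 2L || any(is.na(study_period)) ||
      study_period[1] >= study_period[2]) {
    pim_stop("study_period must be two dates with start < end (half-open [start, end))",
             "pim_validation_error")
  }

  streams <- list(
    patients = as.data.frame(patients),
    prescriptions = as.data.frame(prescriptions),
    conditions = as.data.frame(conditions),
    labs = as.data.frame(labs),
    bp = as.data.frame(bp)
  )
  for (nm in names(streams)) {
    missing_cols <- setdiff(COHORT_STREAMS[[nm]], names(streams[[nm]]))
    if (length(missing_cols)) {
      pim_stop(sprintf("stream '%s' lacks column(s): %s", nm,
                       paste(missing_cols, collapse = ", ")),
               "pim_validation_error")
    }
    streams[[nm]] <- streams[[nm]][, COHORT_STREAMS[[nm]], drop = FALSE]
  }

  diags <- validate_streams(streams)
  if (nrow(diags)) {
    pim_stop(sprintf(
      "cohort validation failed: %d malformed row(s); first: [%s row %d] %s",
      nrow(diags), diags$stream[1], diags$row[1], diags$problem[1]
    ), "pim_validation_error", data = diags)
  }

  pats <- data.table::as.data.table(streams$patients)
  pats[, birth_date := as.Date(birth_date)]
  data.table::setkey(pats, patient_id)

  rx <- data.table::as.data.table(streams$prescriptions)
  rx[, date := as.Date(date)]
  rx[, gtin := ifelse(is.na(gtin) | gtin == "", NA_character_, as.character(gtin))]
  data.table::setorder(rx, patient_id, date, atc, gtin, na.last = TRUE)
  rx[, rid := seq_len(.N)]

  conds <- data.table::as.data.table(streams$conditions)
  conds[, date := as.Date(date)]
  data.table::setorder(conds, patient_id, date, icpc2)

  labs_dt <- data.table::as.data.table(streams$labs)
  labs_dt[, `:=`(date = as.Date(date), egfr = as.numeric(egfr))]
  data.table::setorder(labs_dt, patient_id, date, egfr)

  bp_dt <- data.table::as.data.table(streams$bp)
  bp_dt[, `:=`(date = as.Date(date),
               systolic = as.integer(systolic),
               diastolic = as.integer(diastolic))]
  data.table::setorder(bp_dt, patient_id, date, systolic, diastolic)

  structure(
    list(patients = pats, prescriptions = rx, conditions = conds,
         labs = labs_dt, bp = bp_dt, study_period = study_period),
    class = "pim_cohort"
  )
}

# Row-level invariant checks; returns a diagnostics data.frame
# (stream, row, problem). Row numbers refer to the input row order.
validate_streams <- function(streams) {
  out <- list()
  bad <- function(stream, rows, problem) {
    if (length(rows)) {
      out[[length(out) + 1L]] <<- data.frame(
        stream = stream, row = rows, problem = problem,
        stringsAsFactors = FALSE
      )
    }
  }
  iso_date <- function(x) !is.na(as.Date(as.character(x), optional = TRUE,
                                         tryFormats = "%Y-%m-%d"))

  p <- streams$patients
  bad("patients", which(is.na(p$patient_id) | p$patient_id == ""),
      "empty patient_id")
  bad("patients", which(duplicated(p$patient_id)), "duplicate patient_id")
  bad("patients", which(!p$sex %in% c("female", "male")),
      "sex must be 'female' or 'male'")
  bad("patients", which(!iso_date(p$birth_date)), "unparseable birth_date")

  known <- p$patient_id[!is.na(p$patient_id)]
  birth_of <- as.Date(setNames(as.character(p$birth_date), p$patient_id),
                      optional = TRUE, tryFormats = "%Y-%m-%d")

  check_events <- function(nm, df) {
    bad(nm, which(!df$patient_id %in% known), "unknown patient_id")
    bad(nm, which(!iso_date(df$date)), "unparseable date")
    ok <- df$patient_id %in% known & iso_date(df$date)
    d <- as.Date(as.character(df$date), optional = TRUE, tryFormats = "%Y-%m-%d")
    b <- birth_of[df$patient_id]
    bad(nm, which(ok & !is.na(b) & d < b), "event dated before birth_date")
  }

  rx <- streams$prescriptions
  check_events("prescriptions", rx)
  bad("prescriptions", which(!is_atc(as.character(rx$atc))),
      "atc does not match the bottom-level ATC pattern")
  g <- as.character(rx$gtin)
  bad("prescriptions",
      which(!(is.na(g) | g == "" | is_gtin(g))),
      "gtin must be 8-14 digits or empty")

  cc <- streams$conditions
  check_events("conditions", cc)
  bad("conditions", which(!is_icpc2(as.character(cc$icpc2))),
      "icpc2 does not match the letter+2-digit pattern")

  ll <- streams$labs
  check_events("labs", ll)
  ev <- suppressWarnings(as.numeric(ll$egfr))
  bad("labs", which(is.na(ev) | ev < 0), "egfr must be a non-negative number")

  bb <- streams$bp
  check_events("bp", bb)
  sy <- suppressWarnings(as.integer(bb$systolic))
  di <- suppressWarnings(as.integer(bb$diastolic))
  bad("bp", which(is.na(sy) | is.na(di) | !(sy > di & di > 0)),
      "requires systolic > diastolic > 0")

  if (length(out)) do.call(rbind, out) else
    data.frame(stream = character(), row = integer(), problem = character())
}

#' Read a cohort from interchange files
#'
#' Reads the five delimited-text streams and validates them via
#' [pim_cohort()]. A missing file or unknown/missing column is fatal;
#' malformed rows are collected into a row-numbered diagnostic report and the
#' run aborts if any exist.
#'
#' @param dir Directory containing `patients.csv`, `prescriptions.csv`,
#'   `conditions.csv`, `labs.csv`, `bp.csv`. Alternatively pass `paths`.
#' @param study_period Length-2 `Date` vector, half-open `[start, end)`.
#' @param paths Optional named character vector/list
#'   (`patients`, `prescriptions`, `conditions`, `labs`, `bp`) overriding
#'   `dir`.
#' @return A validated `pim_cohort`.
#' @export
read_cohort <- function(dir = NULL, study_period, paths = NULL) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- file.path(dir, paste0(names(COHORT_STREAMS), ".csv"))
    names(paths) <- names(COHORT_STREAMS)
  }
  paths <- as.list(paths)
  missing_streams <- setdiff(names(COHORT_STREAMS), names(paths))
  if (length(missing_streams)) {
    pim_stop(paste("no path given for stream(s):",
                   paste(missing_streams, collapse = ", ")),
             "pim_io_error")
  }
  tabs <- lapply(names(COHORT_STREAMS), function(nm) {
    path <- paths[[nm]]
    if (!file.exists(path)) {
      pim_stop(sprintf("input file for stream '%s' not found: %s", nm, path),
               "pim_io_error")
    }
    tab <- utils::read.csv(path, colClasses = "character",
                           stringsAsFactors = FALSE)
    if (!identical(names(tab), COHORT_STREAMS[[nm]])) {
      pim_stop(sprintf(
        "header of %s must be exactly: %s (got: %s)", path,
        paste(COHORT_STREAMS[[nm]], collapse = ","),
        paste(names(tab), collapse = ",")
      ), "pim_io_error")
    }
    tab
  })
  names(tabs) <- names(COHORT_STREAMS)
  pim_cohort(tabs$patients, tabs$prescriptions, tabs$conditions, tabs$labs,
             tabs$bp, study_period)
}

#' Write a cohort to interchange files
#'
#' Inverse of [read_cohort()]: writes the five streams as UTF-8 CSV with
#' ISO-8601 dates. Output is deterministic (streams are kept in their sorted
#' order), so identical cohorts produce byte-identical files.
#'
#' @param cohort A `pim_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(df, nm) {
    df <- as.data.frame(df)[, COHORT_STREAMS[[nm]], drop = FALSE]
    for (col in names(df)) {
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    if ("gtin" %in% names(df)) df$gtin[is.na(df$gtin)] <- ""
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE, na = "")
  }
  for (nm in names(COHORT_STREAMS)) write_one(cohort[[nm]], nm)
  invisible(dir)
}

#' Select index prescriptions
#'
#' An index prescription is a prescription dated within the study period and
#' written when the patient was at least `min_age_years` old (completed
#' years). PIM status is assessed per index prescription.
#'
#' @param cohort A `pim_cohort`.
#' @param min_age_years Minimum age at the prescription date; default 65.
#' @return data.table of index prescriptions (`patient_id`, `date`, `atc`,
#'   `gtin`, `rid`, `age_years`), ordered by (patient_id, date, atc).
#' @export
select_index_prescriptions <- function(cohort, min_age_years = 65) {
  stopifnot(inherits(cohort, "pim_cohort"))
  rx <- data.table::copy(cohort$prescriptions)
  rx <- merge(rx, cohort$patients[, .(patient_id, birth_date)],
              by = "patient_id", all.x = TRUE)
  if (anyNA(rx$birth_date)) {
    pim_stop("prescription references unknown patient_id", "pim_validation_error")
  }
  rx[, age_years := age_completed_years(birth_date, date)]
  idx <- rx[date >= cohort$study_period[1] & date < cohort$study_period[2] &
              age_years >= min_age_years]
  data.table::setorder(idx, patient_id, date, atc, gtin, na.last = TRUE)
  idx[, .(patient_id, date, atc, gtin, rid, age_years)]
}
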