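## cli_pipeline: one call from interchange files + rule file to the full
## metrics report, with a machine-readable run manifest. The analysis/
## scripts are thin drivers over this function.

round_pct_cols <- function(df) {
  df <- as.data.frame(df)
  pct <- grep("(_pct|pct_)", names(df))
  for (j in pct) df[[j]] <- round(df[[j]], 1)
  df
}

#' Run the full PIM screening pipeline
#'
#' Reads a cohort (or takes one already in memory), loads rules and
#' products, selects index prescriptions, builds contexts, flags every
#' prescription against every list, computes all metrics, and writes tidy
#' CSV outputs plus a JSON run manifest (package version, configuration,
#' input/output MD5 checksums). Identical inputs yield byte-identical
#' outputs. Progress is logged to stderr.
#'
#' @param input_dir directory with the five interchange files (ignored when
#'   `cohort` is given).
#' @param output_dir directory for result files (created if absent).
#' @param study_period half-open `[start, end)` date pair.
#' @param rules a `pim_rules` object or a rule-file path.
#' @param products a product table or a `products.csv` path.
#' @param cohort optional `pim_cohort`, bypassing `input_dir`.
#' @param class_map a [therapeutic_class_map()] (or CSV path).
#' @param config a [pim_config()].
#' @param top_n ranking depth for the substance ranking.
#' @return invisibly, a list with `flags` and all metric tables.
#' @export
run_screening <- function(input_dir = NULL, output_dir,
                          study_period = as.Date(c("2020-01-01", "2022-01-01")),
                          rules = demo_rules_path(),
                          products = demo_products(),
                          cohort = NULL,
                          class_map = therapeutic_class_map(),
                          config = pim_config(),
                          top_n = 10) {
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    message(sprintf("[pimscreen %5.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    sprintf(fmt, ...)))
  }
  if (is.character(rules)) rules <- load_rule_file(rules)
  if (is.character(products)) products <- read_products(products)
  if (is.character(class_map)) class_map <- read_class_map(class_map)

  input_files <- character()
  if (is.null(cohort)) {
    stopifnot(!is.null(input_dir))
    log_stage("reading cohort from %s", input_dir)
    cohort <- read_cohort(input_dir, study_period)
    input_files <- file.path(input_dir, paste0(names(COHORT_STREAMS), ".csv"))
  }
  log_stage("cohort: %d patients, %d prescriptions",
            nrow(cohort$patients), nrow(cohort$prescriptions))

  flags <- flag_prescriptions(cohort, rules, products, config)
  log_stage("flagged %d index prescriptions (%d combined-PIM)",
            nrow(flags), sum(flags$combined))

  results <- list(
    flags = flags,
    prevalence = pim_prevalence(flags, config$age_cutoffs),
    frequency = pim_frequency(flags),
    burden = pim_burden(flags),
    top_n = pim_top_n(flags, n = top_n),
    class_distribution = pim_class_distribution(flags, class_map),
    overlap_prescriptions = pim_overlap(flags, "prescription"),
    overlap_patients = pim_overlap(flags, "patient")
  )
  log_stage("metrics computed")

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out_files <- character()
  for (nm in names(results)) {
    path <- file.path(output_dir, paste0(nm, ".csv"))
    df <- if (nm == "flags") flags_as_dataframe(flags) else
      round_pct_cols(results[[nm]])
    if ("date" %in% names(df)) df$date <- format(df$date, "%Y-%m-%d")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    out_files <- c(out_files, path)
  }

  manifest <- list(
    package = "pimscreen",
    version = as.character(utils::packageVersion("pimscreen")),
    study_period = format(cohort$study_period, "%Y-%m-%d"),
    config = unclass(config),
    n_patients = nrow(cohort$patients),
    n_prescriptions = nrow(cohort$prescriptions),
    n_index_prescriptions = nrow(flags),
    input_md5 = as.list(tools::md5sum(input_files)),
    output_md5 = as.list(tools::md5sum(out_files))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("wrote %d files to %s", length(out_files) + 1L, output_dir)
  invisible(results)
}
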