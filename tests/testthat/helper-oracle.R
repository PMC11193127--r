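# Independent naive re-implementation of the screening semantics, written
# as plain per-row base-R loops directly from the documented definitions.
# Deliberately shares no code with the package's vectorized path; used to
# cross-check flag_prescriptions() exactly.

oracle_coverage <- function(gtin, products, default_days) {
  i <- match(gtin, products$gtin)
  if (is.na(i)) return(default_days)
  ceiling(products$package_units[i] / products$typical_daily_dose_units[i])
}

oracle_dose <- function(gtin, products) {
  i <- match(gtin, products$gtin)
  if (is.na(i)) return(NA_real_)
  products$unit_strength_mg[i] * products$typical_daily_dose_units[i]
}

oracle_age <- function(birth, date) {
  b <- as.POSIXlt(birth); d <- as.POSIXlt(date)
  a <- d$year - b$year
  if (d$mon < b$mon || (d$mon == b$mon && d$mday < b$mday)) a <- a - 1L
  as.integer(a)
}

oracle_flags <- function(cohort, rules, products, config) {
  products <- as.data.frame(products)
  pats <- as.data.frame(cohort$patients)
  rx <- as.data.frame(cohort$prescriptions)
  conds <- as.data.frame(cohort$conditions)
  labs <- as.data.frame(cohort$labs)
  bp <- as.data.frame(cohort$bp)
  ps <- cohort$study_period[1]; pe <- cohort$study_period[2]
  birth_of <- setNames(pats$birth_date, pats$patient_id)

  rows <- list()
  for (i in seq_len(nrow(rx))) {
    pid <- rx$patient_id[i]; d <- rx$date[i]
    if (d < ps || d >= pe) next
    age <- oracle_age(birth_of[[pid]], d)
    if (age < config$min_age_years) next

    prx <- rx[rx$patient_id == pid, , drop = FALSE]
    # active comedication: half-open coverage windows, index row excluded
    act_atc <- character()
    for (j in seq_len(nrow(prx))) {
      if (prx$rid[j] == rx$rid[i]) next
      cov <- oracle_coverage(prx$gtin[j], products, config$default_coverage_days)
      if (prx$date[j] <= d && d < prx$date[j] + cov) {
        act_atc <- c(act_atc, prx$atc[j])
      }
    }
    act_atc <- unique(act_atc)

    pcc <- conds[conds$patient_id == pid, , drop = FALSE]
    act_icpc <- character()
    for (j in seq_len(nrow(pcc))) {
      chronic <- pcc$icpc2[j] %in% config$chronic_icpc2_codes
      if (pcc$date[j] <= d &&
          (chronic || pcc$date[j] > d - config$condition_lookback_days)) {
        act_icpc <- c(act_icpc, pcc$icpc2[j])
      }
    }
    act_icpc <- unique(act_icpc)

    pll <- labs[labs$patient_id == pid & labs$date <= d &
                  labs$date > d - config$egfr_staleness_days, , drop = FALSE]
    egfr <- if (nrow(pll)) min(pll$egfr[pll$date == max(pll$date)]) else NA_real_

    pbb <- bp[bp$patient_id == pid & bp$date <= d, , drop = FALSE]
    if (config$bp_mode == "latest") {
      if (nrow(pbb)) {
        pbb <- pbb[pbb$date == max(pbb$date), , drop = FALSE]
        pbb <- pbb[order(pbb$systolic, pbb$diastolic), , drop = FALSE]
        bpe <- pbb$systolic[nrow(pbb)] > 140 || pbb$diastolic[nrow(pbb)] > 90
      } else bpe <- FALSE
    } else {
      pbb <- pbb[pbb$date > d - config$bp_window_days, , drop = FALSE]
      bpe <- nrow(pbb) > 0 && any(pbb$systolic > 140 | pbb$diastolic > 90)
    }

    # continuous-use course: running coverage end + grace gap
    same <- prx[prx$atc == rx$atc[i] & prx$date <= d, , drop = FALSE]
    same <- same[order(same$date), , drop = FALSE]
    seg_start <- 1L; seg_end <- -Inf
    covs <- numeric(nrow(same))
    for (j in seq_len(nrow(same))) {
      covs[j] <- oracle_coverage(same$gtin[j], products,
                                 config$default_coverage_days)
      if (as.numeric(same$date[j]) > seg_end + config$grace_gap_days) {
        seg_start <- j
      }
      seg_end <- max(seg_end, as.numeric(same$date[j]) + covs[j])
    }
    in_seg <- seq_len(nrow(same)) >= seg_start
    cum <- sum(covs[in_seg])
    dose <- oracle_dose(rx$gtin[i], products)

    verdict <- setNames(rep(FALSE, 6), names(rules$lists))
    matched <- character()
    for (lid in names(rules$lists)) {
      pl <- rules$lists[[lid]]
      if (age < pl$target_min_age_years) next
      for (r in pl$rules) {
        if (!rx$atc[i] %in% r$trigger_atc) next
        cnd <- r$conditions
        ok <- TRUE
        if (!is.null(cnd$max_daily_dose_mg)) {
          ok <- ok && !is.na(dose) && dose > cnd$max_daily_dose_mg
        }
        if (!is.null(cnd$min_cumulative_use_days)) {
          ok <- ok && cum > cnd$min_cumulative_use_days
        }
        if (!is.null(cnd$required_icpc2_any)) {
          ok <- ok && any(cnd$required_icpc2_any %in% act_icpc)
        }
        if (!is.null(cnd$absent_icpc2_all)) {
          ok <- ok && !any(cnd$absent_icpc2_all %in% act_icpc)
        }
        if (!is.null(cnd$comedication_any)) {
          ok <- ok && any(r$comedication_atc %in% act_atc)
        }
        if (!is.null(cnd$egfr_below)) {
          ok <- ok && !is.na(egfr) && egfr < cnd$egfr_below
        }
        if (!is.null(cnd$bp_elevated_required)) {
          ok <- ok && isTRUE(bpe)
        }
        if (ok) {
          verdict[lid] <- TRUE
          matched <- c(matched, r$rule_id)
        }
      }
    }
    rows[[length(rows) + 1L]] <- c(
      list(patient_id = pid, date = d, atc = rx$atc[i], gtin = rx$gtin[i],
           rid = rx$rid[i]),
      as.list(verdict),
      list(combined = any(verdict), matched_rules = list(sort(matched)))
    )
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r[setdiff(names(r), "matched_rules")])
  }))
  out$matched_rules <- lapply(rows, function(r) r$matched_rules[[1]])
  out[order(out$patient_id, out$date, out$atc, out$gtin), , drop = FALSE]
}

# compare an engine flag table with the oracle's; returns number of
# disagreeing cells/rows
oracle_disagreements <- function(flags, orc) {
  fl <- as.data.frame(flags)  # already in (patient_id, date, atc, gtin) order
  if (is.null(orc)) return(nrow(fl))
  if (nrow(fl) != nrow(orc)) return(max(nrow(fl), nrow(orc)))
  n_bad <- 0L
  lists6 <- c("beers2019", "laroche", "norgep", "priscus", "mann", "eu7")
  for (i in seq_len(nrow(fl))) {
    same_id <- fl$patient_id[i] == orc$patient_id[i] &&
      fl$date[i] == orc$date[i] && fl$atc[i] == orc$atc[i] &&
      identical(is.na(fl$gtin[i]), is.na(orc$gtin[i])) &&
      (is.na(fl$gtin[i]) || fl$gtin[i] == orc$gtin[i])
    same_verdict <- all(vapply(lists6, function(l) fl[[l]][i] == orc[[l]][i],
                               logical(1))) &&
      fl$combined[i] == orc$combined[i]
    same_rules <- identical(sort(flags$matched_rules[[i]]),
                            orc$matched_rules[[i]])
    if (!(same_id && same_verdict && same_rules)) n_bad <- n_bad + 1L
  }
  n_bad
}
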