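## synthetic_cohort: seeded generator of cohorts in the interchange schema.
## Emulates the marginal structure of an older primary-care population
## (age, sex, prescription volume) and plants rule-triggering prescriptions
## constructively, recording rule-level ground-truth labels at generation
## time so the screening engine can be verified end to end. Boundary
## near-misses (dose/eGFR exactly at threshold, age one day below a list's
## gate, condition just outside the lookback, BP exactly at 140/90) are
## planted with expected non-matches to pin the engine's boundary
## semantics.

#' Synthetic cohort configuration
#'
#' Defaults emulate the marginals of a large Swiss primary-care population
#' of older adults: mean age 76.0 (SD 7.9) among patients aged 65+ (the
#' generator solves for the pre-truncation location so the truncated mean
#' hits the target), 55.8% female, and a right-skewed prescription count
#' averaging ~10.5 per patient over the two-year study period. Default
#' per-list planting rates equal the PIM frequencies reported for the six
#' lists (10.3/3.9/4.3/2.4/6.7/9.7%).
#'
#' @param n_patients number of patients.
#' @param age_mean,age_sd,age_min target mean/SD of the (truncated) age
#'   distribution at the study midpoint, and the truncation minimum.
#' @param prop_female fraction of female patients.
#' @param rx_mu,rx_size prescription slots per patient are
#'   `1 + rnbinom(mu = rx_mu, size = rx_size)`.
#' @param planted_rates named per-list probability that a prescription slot
#'   is planted to trigger one of that list's rules (within the list's
#'   age-eligible stratum; see the methods vignette).
#' @param near_miss_rate probability that a slot is a planted boundary
#'   near-miss (expected *not* to match its rule).
#' @param comorbidity_rates named per-rubric background prevalences. Rubrics
#'   used by rule plantings (here D84/D86/A80) must not appear.
#' @param lab_rate,bp_rate expected background lab / BP readings per patient
#'   over the generation span.
#' @param history_rate expected pre-period background prescriptions per
#'   patient (dated 2019), exercising the lookback paths.
#' @param study_period half-open `[start, end)` date pair.
#' @param plant_pool `"all"`: plant any rule of the list (conditions are
#'   constructed to hold). `"exclusive_unconditional"`: restrict to
#'   unconditional rules whose triggers no other list uses — the
#'   configuration for rate-identification experiments, where cross-list
#'   trigger sharing would otherwise confound per-list rates.
#' @param seed integer seed (mandatory: generation is deterministic).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_patients,
                         age_mean = 76.0, age_sd = 7.9, age_min = 65,
                         prop_female = 0.558,
                         rx_mu = 9.45, rx_size = 1.2,
                         planted_rates = c(beers2019 = 0.103, laroche = 0.039,
                                           norgep = 0.043, priscus = 0.024,
                                           mann = 0.067, eu7 = 0.097),
                         near_miss_rate = 0.01,
                         comorbidity_rates = c(K86 = 0.55, L84 = 0.30,
                                               T90 = 0.25, P76 = 0.15,
                                               K78 = 0.10, K77 = 0.08,
                                               P70 = 0.06, U04 = 0.05),
                         lab_rate = 1.5, bp_rate = 2.5, history_rate = 1.0,
                         study_period = as.Date(c("2020-01-01", "2022-01-01")),
                         plant_pool = c("all", "exclusive_unconditional"),
                         seed) {
  plant_pool <- match.arg(plant_pool)
  if (missing(seed) || is.na(seed)) {
    pim_stop("synth_config requires an explicit integer seed", "pim_config_error")
  }
  rates <- setNames(rep(0, length(PIM_LIST_IDS)), PIM_LIST_IDS)
  rates[names(planted_rates)] <- planted_rates
  if (any(rates < 0) || near_miss_rate < 0 ||
      sum(rates) + near_miss_rate > 1) {
    pim_stop("planting rates and near_miss_rate must be >= 0 and sum to <= 1",
             "pim_config_error")
  }
  if (any(comorbidity_rates < 0 | comorbidity_rates > 1)) {
    pim_stop("comorbidity rates must be probabilities", "pim_config_error")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    prop_female = prop_female, rx_mu = rx_mu, rx_size = rx_size,
    planted_rates = rates, near_miss_rate = near_miss_rate,
    comorbidity_rates = comorbidity_rates,
    lab_rate = lab_rate, bp_rate = bp_rate, history_rate = history_rate,
    study_period = as.Date(study_period),
    plant_pool = plant_pool,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# location of the untruncated normal whose left-truncated (at `min`) mean
# equals `target`
trunc_normal_location <- function(target, sd, min) {
  f <- function(mu) {
    a <- (min - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a)) - target
  }
  stats::uniroot(f, c(min - 6 * sd, target + sd), tol = 1e-9)$root
}

rtnorm_min <- function(n, mean, sd, min) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= min])
  }
  out[seq_len(n)]
}

# uniform integer date in [a, b), a/b numeric days since epoch
runif_date <- function(n, a, b) a + floor(stats::runif(n) * (b - a))

pick1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

## -- plant construction tables -----------------------------------------

# per rule: the (atc, gtin) options usable as a planted trigger, honouring a
# dose clause if present; NULL when the rule cannot be constructed from the
# product table
rule_trigger_options <- function(rule, products) {
  prod <- products[atc %in% rule$trigger_atc]
  if (!nrow(prod)) return(NULL)
  if (!is.null(rule$conditions$max_daily_dose_mg)) {
    dose <- prod$unit_strength_mg * prod$typical_daily_dose_units
    prod <- prod[dose > rule$conditions$max_daily_dose_mg]
    if (!nrow(prod)) return(NULL)
  }
  prod[, .(atc, gtin)]
}

# near-miss candidates derivable from a rule set: each row one way to plant
# a prescription expected NOT to match one specific rule
near_miss_candidates <- function(rules, products, config_chronic, min_age) {
  out <- list()
  add <- function(kind, lid, rule, atc, gtin, extra = NA_character_) {
    out[[length(out) + 1L]] <<- list(kind = kind, list_id = lid,
                                     rule_id = rule$rule_id, atc = atc,
                                     gtin = gtin, extra = extra)
  }
  for (lid in names(rules$lists)) {
    plist <- rules$lists[[lid]]
    for (rule in plist$rules) {
      prod <- products[atc %in% rule$trigger_atc]
      if (!nrow(prod)) next
      thr <- rule$conditions$max_daily_dose_mg
      if (!is.null(thr)) {
        at_thr <- prod[prod$unit_strength_mg * prod$typical_daily_dose_units == thr]
        for (i in seq_len(nrow(at_thr))) {
          add("dose_at_threshold", lid, rule, at_thr$atc[i], at_thr$gtin[i])
        }
      }
      if (!is.null(rule$conditions$egfr_below)) {
        add("egfr_at_threshold", lid, rule, prod$atc[1], prod$gtin[1],
            as.character(rule$conditions$egfr_below))
      }
      req <- setdiff(rule$conditions$required_icpc2_any, config_chronic)
      if (length(req)) {
        add("condition_outside_lookback", lid, rule, prod$atc[1],
            prod$gtin[1], req[1])
      }
      if (!is.null(rule$conditions$bp_elevated_required)) {
        add("bp_at_threshold", lid, rule, prod$atc[1], prod$gtin[1])
      }
      if (!length(rule$conditions) && plist$target_min_age_years > min_age) {
        add("age_below_gate", lid, rule, prod$atc[1], prod$gtin[1],
            as.character(plist$target_min_age_years))
      }
    }
  }
  data.table::rbindlist(out)
}

#' Generate a synthetic cohort with constructive ground truth
#'
#' Produces a cohort in the interchange schema plus a ground-truth table
#' recording, for every planted prescription, which rule it was constructed
#' to trigger (`expect_match = TRUE`) or to just miss
#' (`expect_match = FALSE`, boundary near-misses). Ground truth is recorded
#' at generation time from the construction itself, never by running the
#' engine, so engine verification against it is non-circular.
#'
#' Identical seeds and configurations give byte-identical output files.
#'
#' @param config a [synth_config()].
#' @param rules a `pim_rules` object; default the shipped demo rules.
#' @param products product table; default [demo_products()].
#' @param dir if non-NULL, the five interchange files plus `products.csv`
#'   and `ground_truth.csv` are written there.
#' @return list of class `pim_synth`: `cohort` (a `pim_cohort`),
#'   `ground_truth` (data.table), `products`, `config`.
#' @export
generate_cohort <- function(config,
                            rules = load_rule_file(demo_rules_path()),
                            products = demo_products(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"), inherits(rules, "pim_rules"))
  set.seed(config$seed)
  ps <- as.numeric(config$study_period[1])
  pe <- as.numeric(config$study_period[2])
  hist_start <- as.numeric(as.Date("2019-01-01"))
  min_age <- 65L

  ## plant pools per list, validated up front -----------------------------
  pool <- lapply(rules$lists, function(l) l$rules)
  if (config$plant_pool == "exclusive_unconditional") {
    excl <- exclusive_unconditional_rules(rules)
    pool <- lapply(rules$lists, function(l) {
      l$rules[names(l$rules) %in% names(excl)]
    })
  }
  trig_opts <- lapply(pool, function(rs) {
    opts <- lapply(rs, rule_trigger_options, products = products)
    opts[!vapply(opts, is.null, logical(1))]
  })
  for (lid in PIM_LIST_IDS) {
    if (config$planted_rates[[lid]] > 0 && !length(trig_opts[[lid]])) {
      pim_stop(sprintf(
        "infeasible config: list '%s' has planting rate %g but no constructible rule %s",
        lid, config$planted_rates[[lid]],
        "(no rule in the plant pool has a trigger product satisfying its dose clause)"
      ), "pim_config_error")
    }
  }
  # rubrics used for condition-outside-lookback near-misses must never occur
  # in the background, or a background record inside the window could make
  # the near-missed rule fire after all; other rule rubrics are safe (TRUE
  # plants add their own records, absent-clauses are checked per patient)
  chronic_default <- pim_config()$chronic_icpc2_codes
  nm_codes <- unique(unlist(lapply(rules$lists, function(l) {
    unlist(lapply(l$rules, function(r) {
      setdiff(r$conditions$required_icpc2_any, chronic_default)
    }))
  })))
  clash <- intersect(names(config$comorbidity_rates), nm_codes)
  if (length(clash) && config$near_miss_rate > 0) {
    pim_stop(paste("infeasible config: background comorbidity uses",
                   "near-miss-reserved rubric(s):",
                   paste(clash, collapse = ", ")),
             "pim_config_error")
  }
  all_triggers <- unique(unlist(lapply(rules$lists, function(l) {
    unlist(lapply(l$rules, `[[`, "trigger_atc"))
  })))
  background_atc <- sort(setdiff(unique(products$atc), all_triggers))
  if (!length(background_atc)) {
    pim_stop("infeasible config: product table has no non-trigger background substance",
             "pim_config_error")
  }
  nm_cand <- near_miss_candidates(rules, products,
                                  pim_config()$chronic_icpc2_codes, min_age)

  n <- config$n_patients
  empty_cohort <- function() {
    pim_cohort(
      data.frame(patient_id = character(), sex = character(),
                 birth_date = character()),
      data.frame(patient_id = character(), date = character(),
                 atc = character(), gtin = character()),
      data.frame(patient_id = character(), date = character(),
                 icpc2 = character()),
      data.frame(patient_id = character(), date = character(),
                 egfr = character()),
      data.frame(patient_id = character(), date = character(),
                 systolic = character(), diastolic = character()),
      config$study_period
    )
  }
  gt_empty <- data.table::data.table(
    patient_id = character(), date = as.Date(character()), atc = character(),
    gtin = character(), list_id = character(), rule_id = character(),
    expect_match = logical(), kind = character()
  )

  if (n == 0L) {
    out <- structure(list(cohort = empty_cohort(), ground_truth = gt_empty,
                          products = products, config = config),
                     class = "pim_synth")
    if (!is.null(dir)) write_synth(out, dir)
    return(out)
  }

  ## patients --------------------------------------------------------------
  ref <- as.numeric(as.Date("2021-01-01"))  # study midpoint
  mu <- trunc_normal_location(config$age_mean, config$age_sd, config$age_min)
  age <- rtnorm_min(n, mu, config$age_sd, config$age_min)
  pid <- sprintf("P%06d", seq_len(n))
  birth <- ref - round(age * 365.25)
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  b65 <- as.numeric(add_years(as.Date(birth, origin = "1970-01-01"), 65))
  win_lo <- pmax(ps, b65)  # index-eligible window [win_lo, pe)

  ## prescription slots (every slot is an index prescription) --------------
  n_slots <- 1L + stats::rnbinom(n, size = config$rx_size, mu = config$rx_mu)
  slot_pid <- rep.int(seq_len(n), n_slots)
  m <- length(slot_pid)
  slot_date <- runif_date(m, win_lo[slot_pid], pe)
  # category: one of the six lists, a near-miss, or background
  cuts <- cumsum(c(config$planted_rates, config$near_miss_rate))
  cat_idx <- findInterval(stats::runif(m), c(0, cuts), left.open = TRUE)
  # 1..6 = list index, 7 = near miss, 8 = background
  slot_cat <- ifelse(cat_idx <= 6L, cat_idx, ifelse(cat_idx == 7L, 7L, 8L))

  ## background clinical events --------------------------------------------
  com_codes <- names(config$comorbidity_rates)
  com_list <- lapply(seq_along(com_codes), function(k) {
    has <- stats::runif(n) < config$comorbidity_rates[[k]]
    idx <- which(has)
    data.table::data.table(
      pid = idx, date = runif_date(length(idx), hist_start, pe),
      icpc2 = com_codes[k]
    )
  })
  bg_cond <- data.table::rbindlist(com_list)

  n_lab <- stats::rpois(n, config$lab_rate)
  lab_pid <- rep.int(seq_len(n), n_lab)
  bg_lab <- data.table::data.table(
    pid = lab_pid, date = runif_date(length(lab_pid), hist_start, pe),
    egfr = round(pmin(pmax(stats::rnorm(length(lab_pid), 75, 15), 5), 120), 1)
  )

  n_bp <- stats::rpois(n, config$bp_rate)
  bp_pid <- rep.int(seq_len(n), n_bp)
  sys <- round(pmin(pmax(stats::rnorm(length(bp_pid), 138, 18), 95), 230))
  dia <- round(pmin(pmax(stats::rnorm(length(bp_pid), 80, 10), 45), sys - 5))
  bg_bp <- data.table::data.table(pid = bp_pid, date = runif_date(
    length(bp_pid), hist_start, pe), systolic = sys, diastolic = dia)

  n_hist <- stats::rpois(n, config$history_rate)
  hist_pid <- rep.int(seq_len(n), n_hist)
  hist_atc <- background_atc[sample.int(length(background_atc),
                                        length(hist_pid), replace = TRUE)]
  hist_gtin <- vapply(hist_atc, function(a) pick1(products[atc == a, gtin]),
                      "")
  hist_rx <- data.table::data.table(
    pid = hist_pid, date = runif_date(length(hist_pid), hist_start, ps),
    atc = hist_atc, gtin = hist_gtin
  )

  ## planting loop ----------------------------------------------------------
  extra_rx <- list()    # chains, comedication helpers
  plant_rx <- list()    # the planted index prescriptions themselves
  plant_cond <- list()
  plant_lab <- list()
  plant_bp <- list()
  gt <- list()
  lab_drop <- character()  # "pid|date" keys where background labs must yield
  bp_drop <- character()
  used_dates <- vector("list", n)   # per patient: dates already planted
  # planted condition rubrics interact across plants only through the
  # lookback window; track them per patient so a "condition just outside
  # the lookback" near-miss can never be spoiled by (or spoil) another
  # planting of the same rubric
  planted_codes <- vector("list", n)
  nm_codes <- vector("list", n)
  fallback <- integer(0)            # slot indices demoted to background

  draw_plant_date <- function(p, lo) {
    for (i in 1:50) {
      d <- runif_date(1L, lo, pe)
      if (!d %in% used_dates[[p]]) return(d)
    }
    NA_real_
  }

  plant_slots <- which(slot_cat <= 7L)
  for (s in plant_slots) {
    p <- slot_pid[s]
    planted <- FALSE
    if (slot_cat[s] <= 6L) {
      lid <- PIM_LIST_IDS[slot_cat[s]]
      gate <- rules$lists[[lid]]$target_min_age_years
      gate_day <- as.numeric(add_years(as.Date(birth[p], origin = "1970-01-01"),
                                       gate))
      if (gate_day < pe) {  # patient reaches the list's gate within the period
        opts <- trig_opts[[lid]]
        cand_rules <- names(opts)
        cand_rules <- cand_rules[sample.int(length(cand_rules))]
        for (rname in cand_rules) {
          tri <- opts[[rname]]
          d <- draw_plant_date(p, max(win_lo[p], gate_day))
          if (is.na(d)) break
          rule <- pool[[lid]][[rname]]
          k <- sample.int(nrow(tri), 1L)
          tatc <- tri$atc[k]; tgtin <- tri$gtin[k]
          cond <- rule$conditions
          if (!is.null(cond$absent_icpc2_all)) {
            present <- c(planted_codes[[p]], nm_codes[[p]],
                         if (nrow(bg_cond)) bg_cond[pid == p, icpc2])
            if (any(cond$absent_icpc2_all %in% present)) next
          }
          req_code <- NULL
          if (!is.null(cond$required_icpc2_any)) {
            ok_codes <- setdiff(cond$required_icpc2_any, nm_codes[[p]])
            if (!length(ok_codes)) next
            req_code <- pick1(ok_codes)
          }
          # --- construct every clause to hold ---
          if (!is.null(cond$min_cumulative_use_days)) {
            cov <- coverage_days(tgtin, products)
            kpk <- floor(cond$min_cumulative_use_days / cov) + 1L
            if (kpk > 1L) {
              extra_rx[[length(extra_rx) + 1L]] <- list(
                pid = rep(p, kpk - 1L),
                date = d - cov * seq_len(kpk - 1L),
                atc = rep(tatc, kpk - 1L), gtin = rep(tgtin, kpk - 1L)
              )
            }
          }
          if (!is.null(req_code)) {
            plant_cond[[length(plant_cond) + 1L]] <-
              list(pid = p, date = d - 30, icpc2 = req_code)
            planted_codes[[p]] <- c(planted_codes[[p]], req_code)
          }
          if (!is.null(cond$comedication_any)) {
            cp <- products[atc %in% rule$comedication_atc]
            if (!nrow(cp)) next
            j <- sample.int(nrow(cp), 1L)
            extra_rx[[length(extra_rx) + 1L]] <- list(
              pid = p, date = d - 7, atc = cp$atc[j], gtin = cp$gtin[j]
            )
          }
          if (!is.null(cond$egfr_below)) {
            plant_lab[[length(plant_lab) + 1L]] <- list(
              pid = p, date = d, egfr = max(cond$egfr_below - 5, cond$egfr_below / 2)
            )
            lab_drop <- c(lab_drop, paste0(p, "|", d))
          }
          if (!is.null(cond$bp_elevated_required)) {
            plant_bp[[length(plant_bp) + 1L]] <- list(
              pid = p, date = d, systolic = 160, diastolic = 95
            )
            bp_drop <- c(bp_drop, paste0(p, "|", d))
          }
          plant_rx[[length(plant_rx) + 1L]] <-
            list(pid = p, date = d, atc = tatc, gtin = tgtin)
          gt[[length(gt) + 1L]] <- list(
            pid = p, date = d, atc = tatc, gtin = tgtin, list_id = lid,
            rule_id = rule$rule_id, expect_match = TRUE, kind = "planted"
          )
          used_dates[[p]] <- c(used_dates[[p]], d)
          planted <- TRUE
          break
        }
      }
    } else if (nrow(nm_cand)) {
      ## near-miss slot: a lookback near-miss must not reuse a rubric the
      ## patient already has a planted record of (nor vice versa)
      blocked <- c(planted_codes[[p]], nm_codes[[p]])
      cand <- nm_cand[kind != "condition_outside_lookback" | !extra %in% blocked]
      if (nrow(cand)) {
        # feasibility of the age kind depends on the patient
        if (any(cand$kind == "age_below_gate")) {
          keep <- vapply(seq_len(nrow(cand)), function(i) {
            if (cand$kind[i] != "age_below_gate") return(TRUE)
            gd <- as.numeric(add_years(
              as.Date(birth[p], origin = "1970-01-01"),
              as.integer(cand$extra[i])))
            gd - 1 >= win_lo[p] && gd - 1 < pe &&
              !(gd - 1) %in% used_dates[[p]]
          }, logical(1))
          cand <- cand[keep]
        }
        if (nrow(cand)) {
          kinds <- unique(cand$kind)
          kk <- pick1(kinds)
          cand <- cand[kind == kk]
          i <- sample.int(nrow(cand), 1L)
          cm <- as.list(cand[i])
          d <- if (kk == "age_below_gate") {
            as.numeric(add_years(as.Date(birth[p], origin = "1970-01-01"),
                                 as.integer(cm$extra))) - 1
          } else {
            draw_plant_date(p, win_lo[p])
          }
          if (!is.na(d)) {
            if (kk == "egfr_at_threshold") {
              plant_lab[[length(plant_lab) + 1L]] <- list(
                pid = p, date = d, egfr = as.numeric(cm$extra))
              lab_drop <- c(lab_drop, paste0(p, "|", d))
            } else if (kk == "condition_outside_lookback") {
              plant_cond[[length(plant_cond) + 1L]] <- list(
                pid = p, date = d - pim_config()$condition_lookback_days,
                icpc2 = cm$extra)
              nm_codes[[p]] <- c(nm_codes[[p]], cm$extra)
            } else if (kk == "bp_at_threshold") {
              plant_bp[[length(plant_bp) + 1L]] <- list(
                pid = p, date = d, systolic = 140, diastolic = 90)
              bp_drop <- c(bp_drop, paste0(p, "|", d))
            }
            plant_rx[[length(plant_rx) + 1L]] <-
              list(pid = p, date = d, atc = cm$atc, gtin = cm$gtin)
            gt[[length(gt) + 1L]] <- list(
              pid = p, date = d, atc = cm$atc, gtin = cm$gtin,
              list_id = cm$list_id, rule_id = cm$rule_id,
              expect_match = FALSE, kind = kk
            )
            used_dates[[p]] <- c(used_dates[[p]], d)
            planted <- TRUE
          }
        }
      }
    }
    if (!planted) fallback <- c(fallback, s)
  }

  ## background slots ------------------------------------------------------
  bg_slots <- sort(c(which(slot_cat == 8L), fallback))
  bg_atc <- background_atc[sample.int(length(background_atc),
                                      length(bg_slots), replace = TRUE)]
  bg_gtin <- vapply(bg_atc, function(a) pick1(products[atc == a, gtin]), "")
  bg_rx <- data.table::data.table(
    pid = slot_pid[bg_slots], date = slot_date[bg_slots],
    atc = bg_atc, gtin = bg_gtin
  )

  ## assemble streams -------------------------------------------------------
  rx_all <- data.table::rbindlist(c(
    list(bg_rx, hist_rx),
    lapply(plant_rx, data.table::as.data.table),
    lapply(extra_rx, data.table::as.data.table)
  ), use.names = TRUE)

  if (nrow(bg_lab)) {
    bg_lab <- bg_lab[!paste0(pid, "|", date) %in% lab_drop]
  }
  lab_all <- data.table::rbindlist(c(list(bg_lab),
                                     lapply(plant_lab, data.table::as.data.table)),
                                   use.names = TRUE)
  if (nrow(bg_bp)) {
    bg_bp <- bg_bp[!paste0(pid, "|", date) %in% bp_drop]
  }
  bp_all <- data.table::rbindlist(c(list(bg_bp),
                                    lapply(plant_bp, data.table::as.data.table)),
                                  use.names = TRUE)
  cond_all <- data.table::rbindlist(c(list(bg_cond),
                                      lapply(plant_cond, data.table::as.data.table)),
                                    use.names = TRUE)

  as_date <- function(x) as.Date(x, origin = "1970-01-01")
  patients_df <- data.frame(patient_id = pid, sex = sex,
                            birth_date = as_date(birth))
  rx_df <- data.frame(patient_id = pid[rx_all$pid], date = as_date(rx_all$date),
                      atc = rx_all$atc, gtin = rx_all$gtin)
  cond_df <- if (nrow(cond_all)) {
    data.frame(patient_id = pid[cond_all$pid], date = as_date(cond_all$date),
               icpc2 = cond_all$icpc2)
  } else data.frame(patient_id = character(), date = as.Date(character()),
                    icpc2 = character())
  lab_df <- if (nrow(lab_all)) {
    data.frame(patient_id = pid[lab_all$pid], date = as_date(lab_all$date),
               egfr = lab_all$egfr)
  } else data.frame(patient_id = character(), date = as.Date(character()),
                    egfr = numeric())
  bp_df <- if (nrow(bp_all)) {
    data.frame(patient_id = pid[bp_all$pid], date = as_date(bp_all$date),
               systolic = bp_all$systolic, diastolic = bp_all$diastolic)
  } else data.frame(patient_id = character(), date = as.Date(character()),
                    systolic = integer(), diastolic = integer())

  # condition records must not predate birth (possible for deep plant chains
  # or random background draws in extreme ages; clamp is a no-op in practice)
  cond_df$date <- pmax(cond_df$date, as_date(birth)[match(cond_df$patient_id, pid)])

  cohort <- pim_cohort(patients_df, rx_df, cond_df, lab_df, bp_df,
                       config$study_period)

  gt_dt <- if (length(gt)) {
    g <- data.table::rbindlist(lapply(gt, data.table::as.data.table))
    data.table::data.table(
      patient_id = pid[g$pid], date = as_date(g$date), atc = g$atc,
      gtin = g$gtin, list_id = g$list_id, rule_id = g$rule_id,
      expect_match = g$expect_match, kind = g$kind
    )[order(patient_id, date, atc, rule_id)]
  } else gt_empty

  out <- structure(list(cohort = cohort, ground_truth = gt_dt,
                        products = products, config = config),
                   class = "pim_synth")
  if (!is.null(dir)) write_synth(out, dir)
  out
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes the five interchange files plus `products.csv` and
#' `ground_truth.csv`. Deterministic: same bundle, byte-identical files.
#'
#' @param synth a `pim_synth` bundle.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synth <- function(synth, dir) {
  stopifnot(inherits(synth, "pim_synth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(synth$cohort, dir)
  prod <- as.data.frame(synth$products)
  utils::write.csv(prod, file.path(dir, "products.csv"), row.names = FALSE,
                   quote = FALSE)
  gt <- as.data.frame(synth$ground_truth)
  gt$date <- format(gt$date, "%Y-%m-%d")
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Verify engine output against constructive ground truth
#'
#' Joins every ground-truth row to its flag-table row and checks the
#' rule-level expectation: a `TRUE` row's rule id must be among the
#' prescription's matched rules, a near-miss row's must not. A correct
#' engine yields zero discrepancies.
#'
#' @param flags a `pim_flags` table computed on the generated cohort with
#'   the same rules the generator planted against.
#' @param ground_truth the generator's ground-truth table.
#' @return data.table of discrepancies (zero rows when the engine is
#'   correct): ground-truth columns plus `observed_match` and `problem`.
#' @export
verify_ground_truth <- function(flags, ground_truth) {
  stopifnot(inherits(flags, "pim_flags"))
  gt <- data.table::as.data.table(ground_truth)
  if (!nrow(gt)) {
    return(cbind(gt, data.table::data.table(observed_match = logical(),
                                            problem = character())))
  }
  fl <- data.table::as.data.table(flags)
  fl[, row_i := .I]
  key <- c("patient_id", "date", "atc", "gtin")
  gt2 <- merge(gt, fl[, c(key, "row_i"), with = FALSE], by = key,
               all.x = TRUE, sort = FALSE)
  gt2[, observed_match := FALSE]
  found <- !is.na(gt2$row_i)
  gt2$observed_match[found] <- mapply(
    function(i, r) r %in% flags$matched_rules[[i]],
    gt2$row_i[found], gt2$rule_id[found]
  )
  gt2[, problem := data.table::fcase(
    !found, "prescription missing from flag table",
    found & observed_match & !expect_match, "rule matched but expected not to",
    found & !observed_match & expect_match, "rule expected to match but did not",
    default = NA_character_
  )]
  out <- gt2[!is.na(problem)]
  out[, row_i := NULL]
  out[]
}
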