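test_that("generation is deterministic: same seed, byte-identical files", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_cohort(synth_config(n_patients = 40, seed = 99), dir = d1)
  generate_cohort(synth_config(n_patients = 40, seed = 99), dir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the data
  d3 <- tempfile()
  generate_cohort(synth_config(n_patients = 40, seed = 100), dir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "prescriptions.csv"))),
    unname(tools::md5sum(file.path(d3, "prescriptions.csv")))
  ))
})

test_that("zero patients is a valid empty cohort", {
  syn <- generate_cohort(synth_config(n_patients = 0, seed = 1))
  expect_s3_class(syn$cohort, "pim_cohort")
  expect_equal(nrow(syn$cohort$patients), 0L)
  expect_equal(nrow(syn$ground_truth), 0L)
})

test_that("with all planting off, no prescription is ever flagged (negative control)", {
  cfg <- synth_config(n_patients = 80, seed = 12,
                      planted_rates = setNames(rep(0, 6), c(
                        "beers2019", "laroche", "norgep", "priscus", "mann",
                        "eu7")),
                      near_miss_rate = 0)
  syn <- generate_cohort(cfg)
  fl <- flag_prescriptions(syn$cohort, load_rule_file(demo_rules_path()),
                           syn$products)
  expect_gt(nrow(fl), 0)
  expect_false(any(fl$combined))
})

test_that("generated marginals match the configured population", {
  syn <- generate_cohort(synth_config(n_patients = 5000, seed = 2024))
  pats <- syn$cohort$patients
  # continuous age at the study midpoint
  age <- as.numeric(as.Date("2021-01-01") - pats$birth_date) / 365.25
  expect_true(all(age >= 65))
  expect_lt(abs(mean(age) - 76.0), 0.3)
  expect_lt(abs(mean(pats$sex == "female") - 0.558), 0.03)
  # prescription volume: right-skewed, roughly 10.5 slots/patient
  rx_per <- nrow(syn$cohort$prescriptions) / nrow(pats)
  expect_gt(rx_per, 9); expect_lt(rx_per, 13)
})

test_that("an infeasible planting configuration fails with an explanation", {
  # product table lacking any zolpidem strength above the dose thresholds
  rules <- rules_from_list(list(lists = list(priscus = list(rules = list(
    list(rule_id = "zd", trigger = list("N05CF02"),
         conditions = list(max_daily_dose_mg = 5))
  )))))
  weak <- pim_products(data.frame(
    gtin = c("40000001", "40000002"), atc = c("N05CF02", "C07AB02"),
    package_units = 30, unit_strength_mg = 5, typical_daily_dose_units = 1
  ))
  cfg <- synth_config(n_patients = 10, seed = 1,
                      planted_rates = c(priscus = 0.2), near_miss_rate = 0)
  expect_error(generate_cohort(cfg, rules, weak), class = "pim_config_error")
})

test_that("ground-truth verification flags exactly the rows that disagree", {
  syn <- generate_cohort(synth_config(n_patients = 200, seed = 6,
                                      near_miss_rate = 0.05))
  rules <- load_rule_file(demo_rules_path())
  fl <- flag_prescriptions(syn$cohort, rules, syn$products)
  expect_equal(nrow(verify_ground_truth(fl, syn$ground_truth)), 0L)

  # corrupting one ground-truth row produces exactly one discrepancy
  gt_bad <- data.table::copy(syn$ground_truth)
  i <- which(gt_bad$expect_match)[1]
  gt_bad$expect_match[i] <- FALSE
  disc <- verify_ground_truth(fl, gt_bad)
  expect_equal(nrow(disc), 1L)
  expect_equal(disc$rule_id, gt_bad$rule_id[i])

  # simulating an engine without the age gate: forcing the age-near-miss
  # rows to "match" produces discrepancies on exactly those plantings
  nm_age <- syn$ground_truth[kind == "age_below_gate"]
  expect_gt(nrow(nm_age), 0)
  fl2 <- data.table::copy(fl)
  data.table::setattr(fl2, "class", class(fl))
  for (j in seq_len(nrow(nm_age))) {
    k <- which(fl2$patient_id == nm_age$patient_id[j] &
                 fl2$date == nm_age$date[j] & fl2$atc == nm_age$atc[j])
    fl2$matched_rules[[k]] <- c(fl2$matched_rules[[k]], nm_age$rule_id[j])
  }
  disc2 <- verify_ground_truth(fl2, syn$ground_truth)
  expect_equal(nrow(disc2), nrow(nm_age))
  expect_setequal(disc2$kind, "age_below_gate")
})

test_that("every boundary near-miss kind is planted at moderate cohort size", {
  syn <- generate_cohort(synth_config(n_patients = 400, seed = 14,
                                      near_miss_rate = 0.05))
  kinds <- unique(syn$ground_truth$kind[!syn$ground_truth$expect_match])
  expect_true(all(c("dose_at_threshold", "egfr_at_threshold",
                    "condition_outside_lookback", "age_below_gate",
                    "bp_at_threshold") %in% kinds))
})
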