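lists6 <- c("beers2019", "laroche", "norgep", "priscus", "mann", "eu7")

test_that("prevalence is the share of patients with at least one flagged prescription", {
  fl <- make_flags(data.frame(
    patient_id = c("A", "B", "C", "D"),
    date = as.Date("2020-06-01") + 0:3,
    atc = "N05BA06", age_years = c(66L, 71L, 76L, 81L),
    beers2019 = c(TRUE, FALSE, TRUE, FALSE)
  ))
  pv <- pim_prevalence(fl)
  b65 <- pv[pv$list_id == "beers2019" & pv$age_cutoff == 65, ]
  expect_equal(b65$n_patients, 4L)
  expect_equal(b65$n_with_pim, 2L)
  expect_equal(b65$prevalence_pct, 50)
  # all-false flags give 0 everywhere
  none <- make_flags(data.frame(
    patient_id = c("A", "B"), date = as.Date("2020-06-01"),
    atc = "C07AB02", age_years = 70L
  ))
  pn <- pim_prevalence(none)
  expect_true(all(pn$prevalence_pct[pn$n_patients > 0] == 0))
  expect_true(all(is.na(pn$prevalence_pct[pn$n_patients == 0])))
  # empty denominator is reported as NA, not an error
  expect_true(all(is.na(pv$prevalence_pct[pv$age_cutoff == 75 &
                                            pv$n_patients == 0]) |
                    pv$n_patients[pv$age_cutoff == 75] > 0))
})

test_that("prevalence denominators nest and the combined list dominates", {
  fl <- random_flags(400, seed = 31)
  pv <- pim_prevalence(fl)
  for (l in c(lists6, "combined")) {
    np <- pv$n_patients[pv$list_id == l]
    expect_true(all(diff(np) <= 0))  # 65 >= 70 >= 75
  }
  for (a in c(65, 70, 75)) {
    sub <- pv[pv$age_cutoff == a, ]
    comb <- sub$prevalence_pct[sub$list_id == "combined"]
    expect_true(all(comb >= sub$prevalence_pct[sub$list_id != "combined"]))
  }
})

test_that("PIM frequency is the flagged share of prescriptions", {
  fl <- make_flags(data.frame(
    patient_id = "A", date = as.Date("2020-01-01") + 1:10,
    atc = "N05BA06", age_years = 70L,
    beers2019 = rep(c(TRUE, FALSE), c(2, 8))
  ))
  fr <- pim_frequency(fl)
  expect_equal(fr$frequency_pct[fr$list_id == "beers2019"], 20)
  expect_equal(fr$n_prescriptions, rep(10L, 7))
  # combined frequency dominates each individual list on any input
  fr2 <- pim_frequency(random_flags(300, seed = 8))
  comb <- fr2$frequency_pct[fr2$list_id == "combined"]
  expect_true(all(comb >= fr2$frequency_pct[fr2$list_id != "combined"]))
  expect_lte(comb, sum(fr2$frequency_pct[fr2$list_id != "combined"]))
})

test_that("a planted every-5th-prescription design yields exactly 20 percent", {
  n <- 200
  fl <- make_flags(data.frame(
    patient_id = sprintf("P%02d", rep(1:20, each = 10)),
    date = as.Date("2020-01-01") + seq_len(n),
    atc = "A02BC02", age_years = 70L,
    eu7 = (seq_len(n) %% 5) == 0
  ))
  fr <- pim_frequency(fl)
  expect_equal(fr$frequency_pct[fr$list_id == "eu7"], 20)
  expect_equal(fr$frequency_pct[fr$list_id == "combined"], 20)
})

test_that("burden means, SDs and accounting identities hold", {
  fl <- make_flags(data.frame(
    patient_id = rep(c("A", "B"), c(4, 4)),
    date = as.Date("2020-01-01") + 1:8,
    atc = "N05BA06", age_years = 70L,
    mann = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  ))
  bd <- pim_burden(fl)
  row <- bd[bd$list_id == "mann", ]
  expect_equal(row$mean_pims_per_patient, 2)        # counts {4, 0}
  expect_equal(row$sd_pims_per_patient, 2)          # population SD
  expect_equal(row$mean_pct_of_prescriptions, 50)   # {100%, 0%}
  # mean x n_patients equals the total flagged count (accounting identity)
  fl2 <- random_flags(500, seed = 77)
  bd2 <- pim_burden(fl2)
  for (l in c(lists6, "combined")) {
    expect_equal(bd2$mean_pims_per_patient[bd2$list_id == l] *
                   bd2$n_patients[bd2$list_id == l],
                 sum(fl2[[l]]), info = l)
  }
  # a patient with 1 of 10 prescriptions flagged contributes 10%
  one <- make_flags(data.frame(
    patient_id = "A", date = as.Date("2020-01-01") + 1:10,
    atc = "N05BA06", age_years = 70L,
    eu7 = c(TRUE, rep(FALSE, 9))
  ))
  expect_equal(pim_burden(one)[list_id == "eu7", mean_pct_of_prescriptions], 10)
})

test_that("top-N ranks by count with lexicographic ATC tie-break", {
  fl <- make_flags(data.frame(
    patient_id = "A", date = as.Date("2020-01-01") + 1:10,
    atc = c(rep("A02BC02", 4), rep("N05CF02", 3), rep("M01AE01", 3)),
    age_years = 70L, eu7 = TRUE
  ))
  top <- pim_top_n(fl, n = 10)
  eu <- top[top$list_id == "eu7", ]
  expect_equal(eu$atc, c("A02BC02", "M01AE01", "N05CF02"))  # 4, then 3=3 tie
  expect_equal(eu$n_pim, c(4L, 3L, 3L))
  expect_equal(sum(eu$pct_of_all_pims), 100)
  expect_equal(eu$substance_label[1], "Pantoprazole")
  # single-substance table: one entry at 100%
  solo <- make_flags(data.frame(
    patient_id = "A", date = as.Date("2020-01-01") + 1:3,
    atc = "A02BC02", age_years = 70L, beers2019 = TRUE
  ))
  st <- pim_top_n(solo)
  expect_equal(st[st$list_id == "beers2019", pct_of_all_pims], 100)
  # ranking equals a brute-force count over a random table
  fl2 <- random_flags(600, seed = 41)
  top2 <- pim_top_n(fl2, n = 3)
  for (l in lists6) {
    sub <- as.data.frame(fl2)[fl2[[l]], "atc"]
    tab <- sort(table(sub), decreasing = TRUE)
    got <- top2[top2$list_id == l, ]
    expect_equal(got$n_pim[1], as.integer(tab[1]), info = l)
    expect_equal(sum(got$n_pim), sum(head(sort(as.integer(tab),
                                               decreasing = TRUE), 3)),
                 info = l)
  }
})

test_that("class distribution assigns each PIM to exactly one class and sums to 100", {
  fl <- make_flags(data.frame(
    patient_id = "A", date = as.Date("2020-01-01") + 1:4,
    atc = "M01AE01", age_years = 70L, mann = TRUE
  ))
  cd <- pim_class_distribution(fl)
  expect_equal(cd$pct_of_all_pims[cd$class_label == "analgesics"], 100)
  expect_equal(sum(cd$n_pim), 4L)
  # empty flag table: all zeros
  empty <- make_flags(data.frame(
    patient_id = "A", date = as.Date("2020-06-01"), atc = "C07AB02",
    age_years = 70L
  ))
  expect_true(all(pim_class_distribution(empty)$n_pim == 0L))
  # planted composition is recovered exactly
  mix <- make_flags(data.frame(
    patient_id = "A", date = as.Date("2020-01-01") + 1:10,
    atc = c(rep("A02BC02", 5), rep("N05CF02", 3), rep("J01XE01", 2)),
    age_years = 70L, eu7 = TRUE
  ))
  cdm <- pim_class_distribution(mix)
  expect_equal(cdm$n_pim[cdm$class_label == "proton pump inhibitors"], 5L)
  expect_equal(cdm$n_pim[cdm$class_label ==
                           "benzodiazepines and benzodiazepine-like drugs"], 3L)
  expect_equal(cdm$n_pim[cdm$class_label == "other"], 2L)
  expect_equal(max(cdm$cumulative_pct), 100)
})

test_that("overlap counts partition the combined-flagged rows", {
  # all six lists flag the same rows: one subset of size 6
  all6 <- make_flags(data.frame(
    patient_id = "A", date = as.Date("2020-01-01") + 1:5,
    atc = "N05BA06", age_years = 80L,
    beers2019 = TRUE, laroche = TRUE, norgep = TRUE, priscus = TRUE,
    mann = TRUE, eu7 = TRUE
  ))
  ov <- pim_overlap(all6)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$n_lists, 6L)
  expect_equal(ov$n, 5L)
  # disjoint flags: six singleton subsets
  dj <- data.frame(
    patient_id = "A", date = as.Date("2020-01-01") + 1:6,
    atc = "N05BA06", age_years = 80L
  )
  dt <- data.table::as.data.table(dj)
  for (k in seq_along(lists6)) dt[, (lists6[k]) := seq_len(6) == k]
  ovd <- pim_overlap(make_flags(dt))
  expect_equal(nrow(ovd), 6L)
  expect_true(all(ovd$n_lists == 1L))
  # random table: counts equal brute-force enumeration over all 63 subsets
  fl <- random_flags(500, seed = 55)
  ov2 <- pim_overlap(fl)
  expect_equal(sum(ov2$n), sum(fl$combined))
  m <- as.data.frame(fl)[, lists6]
  brute <- table(apply(m, 1, function(r) paste(lists6[as.logical(r)],
                                               collapse = "+")))
  brute <- brute[names(brute) != ""]
  expect_equal(sort(setNames(ov2$n, ov2$subset)),
               sort(setNames(as.integer(brute), names(brute))))
  # patient-level overlap sums to patients with any PIM
  ovp <- pim_overlap(fl, unit = "patient")
  ps <- pimscreen:::patient_flag_summary(fl)
  expect_equal(sum(ovp$n), sum(ps$combined))
})
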