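build_contexts <- pimscreen:::build_contexts

prod1 <- function() {
  pim_products(data.frame(
    gtin = c("30000001", "30000002"), atc = c("N05BA06", "N02AA55"),
    package_units = 30, unit_strength_mg = c(1, 10),
    typical_daily_dose_units = 1
  ))
}

test_that("coverage intervals are half-open [date, date + coverage)", {
  rx <- data.frame(patient_id = "A", date = as.Date("2020-01-01"),
                   atc = "N05BA06", gtin = "30000001", rid = 1L)
  p <- prod1()
  expect_equal(active_medications(rx, as.Date("2020-01-30"), p), "N05BA06") # day 29
  expect_equal(active_medications(rx, as.Date("2020-01-31"), p), character()) # day 30
  expect_equal(active_medications(rx[0, ], as.Date("2020-01-30"), p), character())
})

test_that("overlapping prescriptions are all active; the index row is excluded", {
  rx <- data.frame(
    patient_id = "A", date = as.Date(c("2020-01-01", "2020-01-05")),
    atc = c("N05BA06", "N02AA55"), gtin = c("30000001", "30000002"),
    rid = 1:2
  )
  expect_equal(active_medications(rx, as.Date("2020-01-11"), prod1()),
               c("N02AA55", "N05BA06"))
  expect_equal(active_medications(rx, as.Date("2020-01-11"), prod1(),
                                  exclude_rid = 2L), "N05BA06")
})

test_that("condition activity respects the lookback window and chronic override", {
  d0 <- as.Date("2021-01-01")
  cc <- function(offset, code) {
    data.frame(patient_id = "A", date = d0 - offset, icpc2 = code)
  }
  expect_equal(active_conditions(cc(400, "L84"), d0), character())   # stale
  expect_equal(active_conditions(cc(365, "L84"), d0), character())   # boundary: outside
  expect_equal(active_conditions(cc(364, "L84"), d0), "L84")
  expect_equal(active_conditions(cc(0, "L84"), d0), "L84")           # on index date
  expect_equal(
    active_conditions(cc(5 * 365, "P70"), d0, chronic_icpc2_codes = "P70"),
    "P70"
  )
})

test_that("current eGFR takes the latest value inside the staleness window", {
  d0 <- as.Date("2021-01-01")
  labs <- data.frame(patient_id = "A", date = d0 - c(400, 10),
                     egfr = c(25, 55))
  expect_equal(current_egfr(labs, d0), 55)
  expect_true(is.na(current_egfr(labs[1, ], d0)))          # single stale lab
  expect_true(is.na(current_egfr(labs[0, ], d0)))          # no labs
  # same-day tie: lowest value wins
  tie <- data.frame(patient_id = "A", date = d0, egfr = c(44, 31))
  expect_equal(current_egfr(tie, d0), 31)
})

test_that("elevated BP is strict > 140 systolic or > 90 diastolic on the latest reading", {
  d0 <- as.Date("2021-01-01")
  bb <- function(s, d, off = 0) {
    data.frame(patient_id = "A", date = d0 - off, systolic = s, diastolic = d)
  }
  expect_true(bp_elevated(bb(141, 80), d0))
  expect_false(bp_elevated(bb(140, 90), d0))   # both exactly at threshold
  expect_true(bp_elevated(bb(120, 91), d0))
  expect_false(bp_elevated(bb(120, 80)[0, ], d0))  # no readings
  # only the most recent reading matters
  two <- rbind(bb(180, 110, off = 30), bb(120, 70, off = 1))
  expect_false(bp_elevated(two, d0))
  # inserting even older elevated readings never changes the verdict
  for (off in c(60, 200, 400)) {
    expect_false(bp_elevated(rbind(two, bb(200, 120, off = off)), d0))
  }
  # the windowed mode looks at all readings in the window instead
  expect_true(bp_elevated(two, d0, mode = "any_within_window"))
})

test_that("continuous-use chains sum coverage and break on gaps beyond the grace period", {
  p <- prod1()
  mk <- function(days) data.frame(
    patient_id = "A", date = as.Date("2020-01-01") + days,
    atc = "N05BA06", gtin = "30000001", rid = seq_along(days)
  )
  # refills at 0/30/60 days, 30-day coverage: one 90-day course
  ch <- use_chain(mk(c(0, 30, 60)), as.Date("2020-01-01") + 60, p)
  expect_equal(ch$cumulative_use_days, 90L)
  expect_equal(ch$prior_same_atc_count, 2L)
  # gap beyond coverage + grace breaks the course
  ch2 <- use_chain(mk(c(0, 120)), as.Date("2020-01-01") + 120, p)
  expect_equal(ch2$cumulative_use_days, 30L)
  expect_equal(ch2$prior_same_atc_count, 0L)
  # gap exactly at coverage end + grace still chains (30 + 14)
  ch3 <- use_chain(mk(c(0, 44)), as.Date("2020-01-01") + 44, p)
  expect_equal(ch3$cumulative_use_days, 60L)
  # cumulative use is non-decreasing along a course
  days <- c(0, 25, 55, 80)
  cums <- vapply(days, function(d) {
    use_chain(mk(days[days <= d]), as.Date("2020-01-01") + d, p)$cumulative_use_days
  }, integer(1))
  expect_true(all(diff(cums) >= 0))
})

test_that("build_context assembles all fields for a lone prescription", {
  ch <- mini_cohort(prescriptions = data.frame(
    patient_id = "A", date = as.Date("2020-03-01"),
    atc = "N05BA06", gtin = "30000001"
  ))
  idx <- select_index_prescriptions(ch)
  ctx <- build_context(idx[1], ch, prod1())
  expect_s3_class(ctx, "pim_context")
  expect_equal(ctx$active_atc, character())
  expect_equal(ctx$prior_same_atc_count, 0L)
  expect_equal(ctx$cumulative_use_days, 30L)  # the index package itself
  expect_equal(ctx$age_years, 79L)
  expect_true(is.na(ctx$egfr))
  expect_false(ctx$bp_elevated)
})

test_that("another patient's events never leak into a context", {
  base <- generate_cohort(synth_config(n_patients = 6, seed = 5))
  ch <- base$cohort
  idx <- select_index_prescriptions(ch)
  ctx1 <- build_contexts(ch, idx, base$products, pim_config())
  # drop every other patient's events; contexts for the kept patient unchanged
  keep <- ctx1$patient_id[1]
  sub <- pim_cohort(
    as.data.frame(ch$patients[patient_id == keep]),
    as.data.frame(ch$prescriptions[patient_id == keep])[
      , c("patient_id", "date", "atc", "gtin")],
    as.data.frame(ch$conditions[patient_id == keep]),
    as.data.frame(ch$labs[patient_id == keep]),
    as.data.frame(ch$bp[patient_id == keep]),
    ch$study_period
  )
  idx2 <- select_index_prescriptions(sub)
  ctx2 <- build_contexts(sub, idx2, base$products, pim_config())
  a <- as.data.frame(ctx1[patient_id == keep])
  b <- as.data.frame(ctx2)
  cols <- c("patient_id", "date", "atc", "age_years", "daily_dose_mg", "egfr",
            "bp_elevated", "cumulative_use_days", "prior_same_atc_count")
  expect_equal(a[cols], b[cols], ignore_attr = TRUE)
  expect_equal(a$active_atc, b$active_atc)
  expect_equal(a$active_icpc2, b$active_icpc2)
})
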