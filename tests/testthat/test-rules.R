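ctx0 <- function(...) {
  # a fully-specified context with overridable fields
  defaults <- list(
    patient_id = "A", date = as.Date("2020-06-01"), atc = "N05BA06",
    gtin = NA_character_, rid = 1L, age_years = 80L,
    active_atc = character(), active_icpc2 = character(),
    egfr = NA_real_, bp_elevated = FALSE, daily_dose_mg = NA_real_,
    cumulative_use_days = 30L, prior_same_atc_count = 0L
  )
  utils::modifyList(defaults, list(...))
}

test_that("the shipped demo rule file loads, resolves, and covers every clause kind", {
  rules <- load_rule_file(demo_rules_path())
  expect_s3_class(rules, "pim_rules")
  expect_named(rules$lists,
               c("beers2019", "laroche", "norgep", "priscus", "mann", "eu7"))
  gates <- vapply(rules$lists, `[[`, 0L, "target_min_age_years")
  expect_equal(unname(gates), c(65L, 75L, 70L, 65L, 65L, 65L))
  all_rules <- unlist(lapply(rules$lists, `[[`, "rules"), recursive = FALSE)
  expect_gte(length(all_rules), 40)
  # schema census: every clause kind occurs at least once
  kinds <- unique(unlist(lapply(all_rules, function(r) names(r$conditions))))
  expect_setequal(kinds, c("max_daily_dose_mg", "min_cumulative_use_days",
                           "required_icpc2_any", "absent_icpc2_all",
                           "comedication_any", "egfr_below",
                           "bp_elevated_required"))
  # every trigger expansion is non-empty bottom-level ATC
  for (r in all_rules) {
    expect_true(length(r$trigger_atc) > 0)
    expect_true(all(grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", r$trigger_atc)))
  }
  # every list retains at least one exclusive unconditional rule, so
  # rate-identification experiments are possible for each list
  excl <- pimscreen:::exclusive_unconditional_rules(rules)
  expect_setequal(unique(vapply(excl, `[[`, "", "list_id")),
                  c("beers2019", "laroche", "norgep", "priscus", "mann", "eu7"))
})

test_that("rule files with schema violations fail with rule-level diagnostics", {
  base <- list(lists = list(beers2019 = list(
    target_min_age_years = 65,
    rules = list(list(rule_id = "r1", trigger = list("benzos")))
  )))
  expect_error(rules_from_list(base), class = "pim_rule_error") # unresolved class
  err <- tryCatch(rules_from_list(base), error = function(e) e)
  expect_match(conditionMessage(err), "r1")

  dup <- list(lists = list(beers2019 = list(rules = list(
    list(rule_id = "r1", trigger = list("N05BA06")),
    list(rule_id = "r1", trigger = list("N05BA08"))
  ))))
  expect_error(rules_from_list(dup), class = "pim_rule_error")

  unknown <- list(lists = list(stopp = list(rules = list())))
  expect_error(rules_from_list(unknown), class = "pim_rule_error")

  badthr <- list(lists = list(mann = list(rules = list(
    list(rule_id = "r2", trigger = list("N05BA06"),
         conditions = list(egfr_below = -1))
  ))))
  expect_error(rules_from_list(badthr), class = "pim_rule_error")

  badclause <- list(lists = list(mann = list(rules = list(
    list(rule_id = "r3", trigger = list("N05BA06"),
         conditions = list(weight_below = 50))
  ))))
  expect_error(rules_from_list(badclause), class = "pim_rule_error")
})

test_that("an unconditional rule fires on its trigger substances only", {
  rules <- tiny_rules()
  r <- rules$lists$beers2019$rules$t_benzo
  expect_true(evaluate_rule(r, ctx0(atc = "N05BA06")))
  expect_true(evaluate_rule(r, ctx0(atc = "N05BA08")))
  expect_false(evaluate_rule(r, ctx0(atc = "A02BC02")))
})

test_that("clause comparisons are strict and missing data never trigger", {
  egfr_rule <- tiny_rules()$lists$beers2019$rules$t_egfr
  expect_true(evaluate_rule(egfr_rule, ctx0(atc = "J01XE01", egfr = 25)))
  expect_false(evaluate_rule(egfr_rule, ctx0(atc = "J01XE01", egfr = 30)))  # strict <
  expect_false(evaluate_rule(egfr_rule, ctx0(atc = "J01XE01", egfr = NA_real_)))

  dose_rules <- rules_from_list(list(lists = list(priscus = list(rules = list(
    list(rule_id = "d1", trigger = list("N05CF02"),
         conditions = list(max_daily_dose_mg = 10))
  )))))
  d1 <- dose_rules$lists$priscus$rules$d1
  expect_true(evaluate_rule(d1, ctx0(atc = "N05CF02", daily_dose_mg = 12.5)))
  expect_false(evaluate_rule(d1, ctx0(atc = "N05CF02", daily_dose_mg = 10)))  # strict >
  expect_false(evaluate_rule(d1, ctx0(atc = "N05CF02", daily_dose_mg = NA_real_)))

  other <- rules_from_list(list(
    classes = list(ac = list("B01AA03")),
    lists = list(mann = list(rules = list(
      list(rule_id = "dur", trigger = list("A02BC02"),
           conditions = list(min_cumulative_use_days = 56)),
      list(rule_id = "req", trigger = list("N05AH04"),
           conditions = list(required_icpc2_any = list("P70"))),
      list(rule_id = "abs", trigger = list("A02BC02"),
           conditions = list(absent_icpc2_all = list("D84", "D86"))),
      list(rule_id = "com", trigger = list("M01AE01"),
           conditions = list(comedication_any = list("ac"))),
      list(rule_id = "bp", trigger = list("M01AE01"),
           conditions = list(bp_elevated_required = TRUE))
    )))
  ))$lists$mann$rules
  expect_true(evaluate_rule(other$dur, ctx0(atc = "A02BC02",
                                            cumulative_use_days = 57L)))
  expect_false(evaluate_rule(other$dur, ctx0(atc = "A02BC02",
                                             cumulative_use_days = 56L)))
  expect_true(evaluate_rule(other$req, ctx0(atc = "N05AH04",
                                            active_icpc2 = c("K86", "P70"))))
  expect_false(evaluate_rule(other$req, ctx0(atc = "N05AH04",
                                             active_icpc2 = "K86")))
  expect_true(evaluate_rule(other$abs, ctx0(atc = "A02BC02")))
  expect_false(evaluate_rule(other$abs, ctx0(atc = "A02BC02",
                                             active_icpc2 = "D86")))
  expect_true(evaluate_rule(other$com, ctx0(atc = "M01AE01",
                                            active_atc = "B01AA03")))
  expect_false(evaluate_rule(other$com, ctx0(atc = "M01AE01",
                                             active_atc = "C07AB02")))
  expect_true(evaluate_rule(other$bp, ctx0(atc = "M01AE01", bp_elevated = TRUE)))
  expect_false(evaluate_rule(other$bp, ctx0(atc = "M01AE01")))
})

test_that("the list age gate blocks younger patients; rules combine by OR", {
  rules <- tiny_rules()
  laroche <- rules$lists$laroche
  # a 70-year-old on a Laroche-listed substance is not flagged (gate 75)
  expect_false(evaluate_list(laroche, ctx0(age_years = 70L))$match)
  res <- evaluate_list(laroche, ctx0(age_years = 80L))
  expect_true(res$match)
  expect_equal(res$rule_ids, "t_laroche_benzo")
  # two matching rules are both reported
  two <- rules_from_list(list(lists = list(eu7 = list(rules = list(
    list(rule_id = "a", trigger = list("N05BA06")),
    list(rule_id = "b", trigger = list("N05BA06"))
  )))))
  res2 <- evaluate_list(two$lists$eu7, ctx0())
  expect_true(res2$match)
  expect_setequal(res2$rule_ids, c("a", "b"))
})
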