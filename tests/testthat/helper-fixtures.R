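# In-code fixtures: tiny hand-built cohorts, rule sets and flag tables.

DEFAULT_PERIOD <- as.Date(c("2020-01-01", "2022-01-01"))

# a minimal valid cohort; override any stream
mini_cohort <- function(patients = NULL, prescriptions = NULL,
                        conditions = NULL, labs = NULL, bp = NULL,
                        study_period = DEFAULT_PERIOD) {
  patients <- patients %||% data.frame(
    patient_id = c("A", "B"), sex = c("female", "male"),
    birth_date = as.Date(c("1940-06-15", "1952-01-10"))
  )
  prescriptions <- prescriptions %||% data.frame(
    patient_id = "A", date = as.Date("2020-03-01"),
    atc = "N05BA06", gtin = NA_character_
  )
  conditions <- conditions %||% data.frame(
    patient_id = character(), date = as.Date(character()), icpc2 = character()
  )
  labs <- labs %||% data.frame(
    patient_id = character(), date = as.Date(character()), egfr = numeric()
  )
  bp <- bp %||% data.frame(
    patient_id = character(), date = as.Date(character()),
    systolic = integer(), diastolic = integer()
  )
  pim_cohort(patients, prescriptions, conditions, labs, bp, study_period)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a pim_rules object from an R list using the YAML schema
rules_from_list <- function(x) {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  yaml::write_yaml(x, path)
  load_rule_file(path)
}

# a tiny two-list rule set used by several unit tests
tiny_rules <- function() {
  rules_from_list(list(
    classes = list(benzos = list("N05BA06", "N05BA08")),
    lists = list(
      beers2019 = list(
        target_min_age_years = 65,
        rules = list(
          list(rule_id = "t_benzo", trigger = list("benzos")),
          list(rule_id = "t_egfr", trigger = list("J01XE01"),
               conditions = list(egfr_below = 30))
        )
      ),
      laroche = list(
        target_min_age_years = 75,
        rules = list(
          list(rule_id = "t_laroche_benzo", trigger = list("benzos"))
        )
      )
    )
  ))
}

# construct a pim_flags table directly (for metrics tests)
make_flags <- function(df, matched = NULL) {
  dt <- data.table::as.data.table(df)
  for (l in c("beers2019", "laroche", "norgep", "priscus", "mann", "eu7")) {
    if (is.null(dt[[l]])) dt[, (l) := FALSE]
  }
  if (is.null(dt$gtin)) dt[, gtin := NA_character_]
  if (is.null(dt$rid)) dt[, rid := seq_len(.N)]
  if (is.null(dt$age_years)) dt[, age_years := 70L]
  dt[, combined := beers2019 | laroche | norgep | priscus | mann | eu7]
  dt[, matched_rules := matched %||% rep(list(character()), .N)]
  data.table::setattr(dt, "class", c("pim_flags", class(dt)))
  dt[]
}

# random flag table for property tests
random_flags <- function(n, seed) {
  set.seed(seed)
  atcs <- c("A02BC02", "M01AE01", "N05CF02", "N05BA06", "N02AX02", "C07AB02")
  df <- data.frame(
    patient_id = sprintf("P%02d", sample.int(max(2, n %/% 4), n, replace = TRUE)),
    date = as.Date("2020-01-01") + sample.int(700, n, replace = TRUE),
    atc = sample(atcs, n, replace = TRUE),
    age_years = sample(65:90, n, replace = TRUE)
  )
  dt <- data.table::as.data.table(df)
  for (l in c("beers2019", "laroche", "norgep", "priscus", "mann", "eu7")) {
    dt[, (l) := stats::runif(n) < 0.25]
  }
  dt[, gtin := NA_character_]
  dt[, rid := seq_len(.N)]
  dt[, combined := beers2019 | laroche | norgep | priscus | mann | eu7]
  dt[, matched_rules := rep(list(character()), .N)]
  data.table::setorder(dt, patient_id, date, atc)
  data.table::setattr(dt, "class", c("pim_flags", class(dt)))
  dt[]
}
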