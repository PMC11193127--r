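#!/usr/bin/env Rscript
# Step 2: screen every index prescription against the six PIM lists.
#
# Reads the cohort from results/cohort/, evaluates the shipped demo rule
# file, writes the per-prescription flag table, and verifies the engine
# against the generator's constructive ground truth (the planted rule of
# every planted prescription must match; every boundary near-miss must
# not).

suppressMessages(library(pimscreen))

in_dir <- "results/cohort"
out_dir <- "results/screening"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- read_cohort(in_dir, as.Date(c("2020-01-01", "2022-01-01")))
products <- read_products(file.path(in_dir, "products.csv"))
rules <- load_rule_file(demo_rules_path())

flags <- flag_prescriptions(cohort, rules, products)
write.csv(flags_as_dataframe(flags), file.path(out_dir, "flags.csv"),
          row.names = FALSE, quote = FALSE, na = "")

cat(sprintf("flagged %d index prescriptions from %d patients\n",
            nrow(flags), length(unique(flags$patient_id))))
for (l in c("beers2019", "laroche", "norgep", "priscus", "mann", "eu7",
            "combined")) {
  cat(sprintf("  %-10s %6d flagged (%.1f%%)\n", l, sum(flags[[l]]),
              100 * mean(flags[[l]])))
}

gt <- read.csv(file.path(in_dir, "ground_truth.csv"),
               colClasses = c(date = "Date"))
gt$gtin <- as.character(gt$gtin)
disc <- verify_ground_truth(flags, gt)
cat(sprintf("ground-truth check: %d plantings, %d discrepancies\n",
            nrow(gt), nrow(disc)))
if (nrow(disc)) {
  write.csv(disc, file.path(out_dir, "ground_truth_discrepancies.csv"),
            row.names = FALSE)
  stop("engine output disagrees with constructive ground truth")
}
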