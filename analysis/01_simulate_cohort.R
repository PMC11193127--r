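#!/usr/bin/env Rscript
# Step 1: simulate the study population.
#
# Generates the default synthetic primary-care cohort (2000 patients aged
# 65+, two-year study period 2020-2021, demographics and prescription
# volume emulating a large Swiss primary-care population) together with its
# constructive ground-truth labels, and writes the interchange files to
# results/cohort/.

suppressMessages(library(pimscreen))

seed <- 20240601L
out_dir <- "results/cohort"

cfg <- synth_config(n_patients = 2000, seed = seed)
syn <- generate_cohort(cfg, dir = out_dir)

ch <- syn$cohort
age <- as.numeric(as.Date("2021-01-01") - ch$patients$birth_date) / 365.25
cat(sprintf("cohort written to %s\n", out_dir))
cat(sprintf("  patients:        %d (%.1f%% female)\n", nrow(ch$patients),
            100 * mean(ch$patients$sex == "female")))
cat(sprintf("  mean (SD) age:   %.1f (%.1f) years\n", mean(age), sd(age)))
cat(sprintf("  prescriptions:   %d (%.1f per patient)\n",
            nrow(ch$prescriptions),
            nrow(ch$prescriptions) / nrow(ch$patients)))
cat(sprintf("  conditions/labs/BP records: %d / %d / %d\n",
            nrow(ch$conditions), nrow(ch$labs), nrow(ch$bp)))
cat(sprintf("  ground-truth plantings: %d (%d boundary near-misses)\n",
            nrow(syn$ground_truth), sum(!syn$ground_truth$expect_match)))
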