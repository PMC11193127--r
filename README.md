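# pimscreen

Screening longitudinal primary-care prescription records for **potentially
inappropriate medication (PIM)** with explicit criteria lists, and computing
the pharmacoepidemiological metrics that describe the result.

## The problem

Older adults are routinely prescribed drugs whose risks likely outweigh their
benefits. Several expert panels have published *explicit PIM lists* —
Beers 2019 (US), Laroche (France), NORGEP (Norway), PRISCUS (Germany),
Mann (Austria) and the European EU(7) consensus list — that name the
substances and the circumstances (dose, duration of use, comorbidity,
comedication, blood pressure, kidney function) under which a prescription is
considered inappropriate, each behind its own minimum target age
(Beers/PRISCUS/Mann/EU(7) ≥65, NORGEP ≥70, Laroche ≥75 years).

Applying such lists to electronic health-record data is mostly an
operationalization problem: criteria must be translated into machine-checkable
conditions on what is actually recorded — ATC-coded prescriptions with GTIN
package identifiers, ICPC-2-coded reasons for encounter, eGFR laboratory
values and blood-pressure readings. `pimscreen` provides that machinery as a
reusable, tested pipeline:

1. **Index prescriptions.** Every prescription written during the study
   period at patient age ≥65 (completed years) is assessed individually.
2. **Context reconstruction.** For each index prescription the patient's
   state at that date is rebuilt: age; *active comedication* from package-size
   exposure windows (`[date, date + package_units / typical_daily_dose)`,
   chained across refills with a 14-day grace gap); *active conditions* from a
   365-day lookback with a chronic-rubric override; the most recent eGFR
   within a one-year staleness window; and an elevated-BP flag (most recent
   reading, systolic > 140 or diastolic > 90 mm Hg, strict).
3. **Rule evaluation.** Criteria are declarative YAML rules: a trigger set of
   bottom-level ATC codes (or named drug classes, expanded as enumerated
   substance sets) plus a conjunction of condition clauses. A prescription is
   PIM for a list iff the list's age gate passes and at least one rule fires;
   it is PIM for the *combined list* iff at least one of the six lists flags
   it. Missing data (unknown GTIN, no current eGFR) never satisfy a clause.
4. **Metrics.** Age-stratified period prevalence (share of patients with ≥1
   PIM, at cutoffs 65/70/75 using age at first index prescription), PIM
   frequency (share of prescriptions flagged), per-patient burden
   (mean/SD count and share of own prescriptions), top-N substance rankings,
   therapeutic drug-class distribution, and exact list-overlap counts.

Because real primary-care databases of this kind are not public, the package
ships a seeded **synthetic cohort generator** that emulates the interchange
schema and population marginals, and — crucially — records *constructive
ground truth*: for every planted prescription, which rule it was built to
trigger, or to *just miss* (dose or eGFR exactly at threshold, age one day
below a list's gate, condition just outside the lookback window). The engine
is verified end-to-end against these labels and against an independent naive
evaluator.

The shipped rule file (`inst/extdata/rules_demo.yaml`, ~48 rules) is an
illustrative, machine-readable subset covering every clause kind — **not** a
clinically complete transcription of any published list. Real analyses supply
their own complete rule files in the documented schema.

## Worked example

```r
library(pimscreen)

syn   <- generate_cohort(synth_config(n_patients = 200, seed = 7))
rules <- load_rule_file(demo_rules_path())
flags <- flag_prescriptions(syn$cohort, rules, syn$products)

pim_frequency(flags)
#>      list_id n_prescriptions n_pim frequency_pct
#> 1: beers2019            2189   361     16.491549
#> 2:   laroche            2189   214      9.776153
#> 3:    norgep            2189   231     10.552764
#> 4:   priscus            2189   217      9.913202
#> 5:      mann            2189   317     14.481498
#> 6:       eu7            2189   456     20.831430
#> 7:  combined            2189   812     37.094564

prev <- pim_prevalence(flags)
prev[prev$list_id == "combined"]
#>     list_id age_cutoff n_patients n_with_pim prevalence_pct
#> 1: combined         65        200        168       84.00000
#> 2: combined         70        160        140       87.50000
#> 3: combined         75        109         96       88.07339

top <- pim_top_n(flags, n = 3)
top[top$list_id == "combined"]
#>     list_id  rank     atc substance_label n_pim pct_of_all_pims
#> 1: combined     1 M01AE01       Ibuprofen    70        8.620690
#> 2: combined     2 N05CF02        Zolpidem    59        7.266010
#> 3: combined     3 N06DX02   Ginkgo folium    51        6.280788

nrow(verify_ground_truth(flags, syn$ground_truth))  # engine vs planted labels
#> [1] 0
```

Reading: of the 2,189 index prescriptions written to these 200 synthetic
patients, 37.1% are PIM according to at least one list (ranging from 9.8%
under Laroche to 20.8% under EU(7)); 84% of patients received at least one
PIM, rising with age; and the most frequently planted PIM substances are
recovered in the ranking. The final line confirms that every planted rule
fired and every boundary near-miss did not. (Absolute levels reflect the
generator's default planting rates and the demo rule subset, not any real
population.)

## Analysis workflow

Numbered drivers under `analysis/` run the full study on a 2,000-patient
cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort + ground truth -> results/cohort/
Rscript analysis/02_flag_prescriptions.R  # flag table + ground-truth check
Rscript analysis/03_metrics.R             # all metric tables -> results/metrics/
Rscript analysis/04_rate_recovery.R       # planted-rate recovery experiment
```

`run_screening()` performs the read → flag → metrics chain in one call and
writes a JSON run manifest (package version, configuration, input/output MD5
checksums) alongside the tables.

## Repository layout

```
R/                 package code: cohort model, drug knowledge, temporal
                   context, criteria engine, metrics, synthetic generator,
                   pipeline
inst/extdata/      rules_demo.yaml — demo criteria rule file (schema docs inside)
tests/testthat/    unit, property and acceptance tests (incl. the
                   independent naive evaluator in helper-oracle.R)
analysis/          numbered workflow drivers
scripts/           acceptance.R
vignettes/         methods vignette: model, policies, generator design
```
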