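---
title: "Methods: explicit-criteria PIM screening on longitudinal prescription records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explicit-criteria PIM screening on longitudinal prescription records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pimscreen)
```

## The screening model

`pimscreen` decides, for every *index prescription*, whether it is a
potentially inappropriate medication (PIM) according to each of six explicit
criteria lists (Beers 2019, Laroche, NORGEP, PRISCUS, Mann, EU(7)) and their
union, the *combined list*. An index prescription is any prescription dated
inside the half-open study period `[start, end)` and written when the patient
was at least 65 in completed years. Screening is per prescription, not per
patient: the same substance can be appropriate in January and inappropriate
in December if the patient's situation changed.

The decision for one prescription uses only the patient's state at that date
(the *prescription context*):

* **age** in completed years (the birthday convention; a Feb-29 birthday
  increments on Mar 1 in non-leap years);
* **active comedication** — every other prescription whose exposure window
  covers the index date. A package's window is
  `[date, date + ceiling(package_units / typical_daily_dose_units))`, both
  quantities taken from the GTIN product record; an unknown or missing GTIN
  falls back to `default_coverage_days`;
* **cumulative use** of the index substance — same-ATC prescriptions are
  merged into continuous courses: a refill extends the course when its date
  is at most `grace_gap_days` after the running maximum coverage end;
  cumulative use is the summed coverage of the course through the index date;
* **active conditions** — ICPC-2 rubrics recorded in
  `(index − condition_lookback_days, index]`, with a configurable set of
  chronic rubrics active from their first record onward;
* **kidney function** — the most recent eGFR in
  `(index − egfr_staleness_days, index]`, otherwise undefined;
* **blood pressure** — elevated iff the most recent reading on or before the
  index has systolic > 140 or diastolic > 90 mm Hg (strict inequalities);
  configurable to "any reading within a window".

A criteria rule is a trigger set of bottom-level ATC codes (classes are
*enumerated* substance sets — no prefix wildcarding, so fixed combinations
like tramadol + paracetamol must be listed explicitly) plus a conjunction of
clauses: `max_daily_dose_mg`, `min_cumulative_use_days`,
`required_icpc2_any`, `absent_icpc2_all`, `comedication_any`, `egfr_below`,
`bp_elevated_required`. Disjunctive criteria are written as several rules
sharing a trigger. A list flags a prescription iff its age gate passes
(Laroche ≥75, NORGEP ≥70, others ≥65) and at least one rule fires.

### Policy choices and their rationale

Several details are under-determined by how criteria lists are published;
the package fixes them explicitly and exposes each as configuration
(`pim_config()`):

| parameter | default | rationale |
|---|---|---|
| `condition_lookback_days` | 365 | a recorded reason for encounter is taken as clinically current for a year; chronic rubrics (dementia P70, diabetes T89/T90, heart failure K77 by default) never expire |
| `egfr_staleness_days` | 365 | a kidney-function value older than a year should not gate a renal criterion; the window is half-open, so a lab exactly 365 days old is stale |
| `grace_gap_days` | 14 | refills are rarely perfectly contiguous; two weeks tolerates dispensing slack without merging genuinely separate courses |
| `default_coverage_days` | 30 | a one-month package is the modal dispensed size |
| `bp_mode` | `"latest"` | the most recent reading is the clinically current one; `"any_within_window"` is available for sensitivity analyses |
| dose/eGFR comparisons | strict `>` / `<` | documented so rule authors can encode either convention by adjusting thresholds |

Missing data are *non-triggering* throughout: a clause that needs a daily
dose (unknown GTIN) or an eGFR (no current lab) evaluates false, so the rule
cannot fire. This is deliberately conservative — screening never accuses on
data it does not have.

Two tie-break rules cover same-day measurements, which published criteria
never discuss: among labs on the latest date the *lowest* eGFR wins
(conservative for renal gates); among BP readings on the latest date the one
with the highest systolic (then diastolic) wins. Both are deterministic so
that repeated runs are bit-identical.

Two age conventions coexist by design: the *list age gate* applies per
prescription (age at the prescription date), while *age-stratified metrics*
assign each patient to a stratum by age at their first index prescription.
A patient crossing a list's gate mid-period therefore contributes flags only
from the crossing onward, which is why a high-gate list's numerator can be
identical at cutoffs below its gate while the denominators shrink.

## Metrics

All metrics are pure functions of the flag table (plus the cohort):

* **prevalence** — share of patients with ≥1 flagged prescription, per list
  and cutoff (65/70/75); denominators use age at first index prescription;
* **frequency** — share of index prescriptions flagged;
* **burden** — per-patient PIM count and share of the patient's own
  prescriptions, averaged over *all* included patients (zero-PIM patients
  included). The SD is the population SD (divisor *n*); at cohort scale the
  difference from the sample SD is negligible, and the choice is documented
  rather than consequential;
* **top-N ranking** — counts per bottom-level ATC, ties broken by ATC code
  ascending (a documented, arbitrary but deterministic rule);
* **class distribution** — every combined-flagged prescription is assigned
  to exactly one therapeutic class by ATC prefix (prefixes are validated to
  be pairwise non-nested; unmatched codes fall into `"other"` rather than
  erroring, since reporting maps are intentionally coarse);
* **overlap** — exact-subset counts over the six lists, at prescription or
  patient level; subset counts sum to the combined total by construction.

Percentages are stored unrounded and rounded to one decimal only in written
output.

## The synthetic cohort generator

Real primary-care EHR databases of this kind are access-restricted, so the
package generates cohorts in the same interchange schema. The generator
emulates *marginals* of an older primary-care population: age at the study
midpoint is drawn from a left-truncated normal (target mean 76.0 years, SD
7.9, minimum 65 — the generator solves for the pre-truncation location so
the *truncated* mean hits the target; the realized SD is consequently
somewhat below the nominal 7.9, a deliberate simplification of calibrating
location only), 55.8% of patients are female, and prescription counts per
patient are negative-binomial with mean ≈ 10.5 over the two-year period.
Background prescriptions are drawn from substances no demo rule triggers;
2019-dated history prescriptions exercise the lookback paths. Default
per-list planting rates (10.3/3.9/4.3/2.4/6.7/9.7%) mirror the relative
order of magnitude reported for these lists in large primary-care data.

What the generator does **not** emulate: multimorbidity correlation
structure, market shares, seasonality, prescriber effects, or any real
population's absolute PIM levels. Passing tests therefore demonstrate that
the *engine* is correct, not that the synthetic numbers describe any real
cohort — with the demo rule subset and overlapping trigger sets, realized
per-list frequencies exceed the planting rates (a prescription planted for
one list often legitimately fires another list's rule on the same
substance).

### Constructive ground truth

Every planted prescription records, at generation time, the rule it was
built to trigger — substance and GTIN chosen to satisfy a dose clause,
refill chains long enough for duration clauses, condition/comedication/lab/
BP records inserted as needed. Near-misses are planted the same way but
built to *fail* one specific rule at its boundary: dose exactly at the
threshold, eGFR exactly at the threshold, the required condition recorded
exactly `lookback` days before the index (just outside the half-open
window), BP exactly 140/90, or the prescription dated one day before the
patient crosses a list's age gate. Labels are rule-level, not list-level,
because only the named rule's behaviour is constructively guaranteed — a
planted substance may legitimately fire other rules. `verify_ground_truth()`
checks every label against the engine's matched-rule sets; the engine is
also cross-checked, row by row, against an independent naive evaluator
written directly from the definitions above (a plain-loop re-implementation
kept in the test helpers, sharing no code with the vectorized engine).

### The rate-recovery experiment

Recovering a configured per-list planting rate from engine output is only
well-posed if a planted prescription can be flagged by its own list alone,
and only within the stratum where planting is possible:

* plants are restricted to *exclusive unconditional* rules — rules without
  clauses whose trigger substances no other list uses
  (`plant_pool = "exclusive_unconditional"`); with shared triggers the
  measured rates would confound by construction, not by engine error;
* a list with an age gate above 65 can only be planted for patients who
  reach the gate within the period, so the measured frequency is computed
  within that age-eligible stratum. There the flagged count is exactly
  binomial in the number of eligible prescription slots, giving the
  3-standard-error acceptance band its exact meaning.

`analysis/04_rate_recovery.R` runs this design at rates 2/5/10% with about
50,000 prescriptions per run.

## Problem sizes and determinism

The test suite exercises: exact oracle equivalence on twenty random cohorts
of 30–100 patients; full ground-truth recovery (including all five
near-miss kinds) on a 2,000-patient cohort; rate recovery at ~50,000
prescriptions; and byte-identical regeneration and pipeline reruns under a
fixed seed. These sizes were chosen so the entire suite and the analysis
scripts complete comfortably on a single CPU while keeping every binomial
band tight enough to be informative. All randomness flows through a single
mandatory integer seed; file output is sorted and formatted deterministically.

## Known limitations

* The shipped rule file is an illustrative subset with illustrative
  thresholds; clinical completeness of any list is explicitly out of scope,
  and screening results with it characterize the engine, not practice.
* Dose handling is mg-only and uses the product's *typical* daily dose, not
  the prescribed regimen (free-text dosing is not parsed). Combination
  products are compared on the rule-designated active only.
* Duration of use is reconstructed from refill chains; actual adherence,
  tapering and stockpiling are not modelled.
* Condition semantics rest on coded reasons for encounter; severity,
  resolution and free-text problem lists are out of scope.
* The BP and eGFR tie-break and staleness policies are package policy, made
  explicit because source criteria do not define them; sensitivity to these
  choices can be probed through `pim_config()`.
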