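Package: pimscreen
Title: Screening Prescriptions for Potentially Inappropriate Medication with
    Explicit Criteria Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative rule engine and metrics suite for screening
    longitudinal primary-care prescription records against explicit
    potentially-inappropriate-medication (PIM) criteria lists (Beers 2019,
    Laroche, NORGEP, PRISCUS, Mann, EU(7)). Reconstructs each patient's state
    at every index prescription (age, active comedication from package-size
    exposure windows, active conditions, latest eGFR, elevated blood
    pressure), evaluates machine-readable criteria rules per list, and
    computes age-stratified PIM prevalence, PIM frequency, per-patient
    burden, top-N substance rankings, therapeutic drug-class distribution
    and list-overlap counts. Ships a seeded synthetic EHR cohort generator
    with constructive ground-truth labels so the whole pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
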