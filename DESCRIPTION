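Package: sepsisval
Title: Electronic Phenotyping and Validation of EHR Sepsis Alerts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for externally validating electronic health record (EHR)
    sepsis alerting systems against a Sepsis-3 electronic phenotype. Computes
    Sequential Organ Failure Assessment (SOFA) organ sub-scores and totals on
    a 15-minute grid with bounded last-observation-carried-forward imputation,
    labels sepsis onset as the first two-point SOFA increase in encounters
    with blood-culture and antibiotic orders, evaluates fired alerts with
    windowed and whole-encounter confusion matrices and Wilson confidence
    intervals, benchmarks alerts against a Monte-Carlo random-alert null,
    summarises alert-to-onset lead times, and tabulates cohort
    characteristics with chi-square tests. A synthetic-cohort generator
    plants known onset and alert structure so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
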