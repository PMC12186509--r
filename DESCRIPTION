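Package: vwecon
Title: Hospital and Payer Economics of All-Virtual Hospital-at-Home Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-consequence and budget-impact modelling for all-virtual
    hospital-at-home ("virtual ward") acute-care programs. Builds
    hospital-perspective ledgers of avoided variable costs, lost inpatient
    revenue by reimbursement mechanism (DRG-based, per-diem, flat daily rate,
    capitated), and program fixed costs; projects per-patient rates onto
    arbitrary payer mixes and variable-cost scalings; solves break-even payer
    mixes and reimbursement thresholds for hospital cost neutrality; and
    models payer-perspective per-case costs with quality-of-life adjustment
    and payer-neutrality reimbursement thresholds. Includes a seeded synthetic
    patient-encounter generator with closed-form calibration so the whole
    pipeline is testable end-to-end without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
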