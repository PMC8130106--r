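Package: cpapcost
Title: Cost-Minimization and Budget-Impact Analysis of Internalized CPAP Provision
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative cost analysis of hospital-internalized versus
    outsourced provision of continuous positive airway pressure (CPAP)
    therapy for sleep apnea-hypopnea syndrome. Implements exact
    cent-precision currency arithmetic, piecewise tariff-segmented
    accrual of outsourced per-device-day rental costs, bottom-up
    microcosting of the internalized service (devices, consumables,
    nursing time), headline comparison metrics (total and subgroup
    savings, cost per device-day), a multi-year budget-impact projection
    with deterministic device-price sensitivity scenarios,
    contingency-table analysis of patient-satisfaction surveys, and a
    seeded synthetic cohort generator for pipeline testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
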