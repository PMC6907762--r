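Package: dutyhours
Title: Duty-Hour Violation Detection from EHR Access Logs and Self-Reports
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers clinician work shifts from electronic health record (EHR)
    access-log timestamps by gap-threshold sessionization, evaluates
    ACGME-style duty-hour rules (maximum shift duration and minimum
    inter-shift rest) over both EHR-defined and self-reported shifts,
    aggregates violations to resident-blocks, and quantifies systematic
    under-reporting by pairing self-reported with EHR-defined violation
    tallies. Includes a fully seeded synthetic-data generator (schedules,
    within-shift event processes, biased self-reporting) so the whole
    pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
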