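Package: adewatch
Title: Forecast Adverse Drug Event Risk from Trial Exclusions and Linked
    Administrative Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A three-part pharmacovigilance pipeline for newly released
    drugs. Structures the exclusion criteria of a drug's pre-release
    clinical trials into a per-indication exclusion profile, profiles the
    drug's real-world target population from person-linked pharmaceutical
    dispensing and hospital morbidity records (diagnosis code-set matching
    across ICD coding eras, high-use medication filtering, a
    medication/morbidity classification lattice, age-band by sex
    cross-tabulations), and compares the two profiles to flag patient
    groups carrying trial-excluded comorbidities or co-medications as
    potentially at risk of an adverse drug event. Includes a seeded
    synthetic generator for person-level linked records so every stage is
    testable without access to restricted administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
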