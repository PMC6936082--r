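Package: idenhance
Title: Enhancement of Indigenous Status Identification in Linked Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enhancing the identification of Aboriginal and Torres
    Strait Islander people across person-linked administrative health datasets
    (cancer registry, hospital admissions, emergency department and cause-of-death
    collections), and for quantifying the impact of enhancement on cancer case
    counts and directly age-standardised incidence rates. Implements the
    ever-reported, most-recent-record, weight-of-evidence and multi-stage-median
    enhancement algorithms with registry and death-certificate precedence rules,
    direct age-standardisation to the 2001 Australian standard population with
    gamma (Dobson-type) confidence intervals, and a seeded synthetic linked-cohort
    simulator for validating the pipeline without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
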