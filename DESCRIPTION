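Package: sbdhscreen
Title: Screening Electronic Health Records for Social and Behavioral
    Determinants of Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the availability of social and behavioral
    determinants of health (SBDH) in electronic health record (EHR) data.
    Provides per-field completeness metrics for structured EHR tables,
    ICD-code cohort queries for SBDH diagnoses (social connection and
    isolation, housing issues, financial resource strain), a rule-based
    text miner that locates SBDH phrases in clinical notes and classifies
    each occurrence's context (including SmartPhrase question/answer
    negation), an annotation evaluation scheme for manually reviewed
    notes, and a synthetic-EHR generator that emulates the statistical
    structure of a large multilevel health system so the whole pipeline
    can be exercised and validated without access to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
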