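Package: pgxcea
Title: Cost-Effectiveness of Pharmacogenomics-Guided Prescribing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cohort model quantifying gene-drug-related
    deaths prevented and the cost per death prevented when
    pharmacogenomics (PGx)-guided dose and drug selection is adopted
    nation-wide for "essential" drug-gene interactions. Ships the Dutch
    seven-drug portfolio (clopidogrel-CYP2C19, fluoropyrimidines-DPYD,
    thiopurines-TPMT, irinotecan-UGT1A1) with a per-field provenance
    ledger, a patient-level Monte-Carlo microsimulation oracle, a
    synthetic portfolio generator, and one-way, threshold and
    probabilistic sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
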