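Package: aersrank
Title: Prescription-Normalized Ranked-Risk Analysis of Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pharmacovigilance pipeline for AERS/FAERS-style
    spontaneous adverse-event report extracts. Reads legacy dollar-delimited
    quarterly tables (demographics, drug mentions with suspect-role codes,
    coded reaction terms, outcome codes, report sources), consolidates drug
    name variants through a synonym dictionary with optional edit-distance
    matching, removes follow-up versions and heuristic duplicate case
    reports, matches reports against named adverse-event categories, and
    computes report counts by suspect role, prescribing ratios from
    new-prescription (NRx) denominators, normalized reporting rates, and
    ranked risks scaled to the highest-rate drug. Includes yearly trend and
    outcome/reporter stratifications, a synthetic report generator with
    ground-truth labels for end-to-end validation, and a one-command
    pipeline driver. Ships a curated statin synonym dictionary, muscle
    adverse-event category definitions, and the published statin NRx totals
    as worked-example inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
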