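Package: linkenhance
Title: Enhanced Reporting of Indigenous Status from Linked Administrative Health Records
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a person-level Indigenous status from linked
    administrative health records using record-linkage enhancement rules
    (ever/always reported, index and most recent record, majority of
    admissions, at least two hospitals, the Enhanced Reporting of
    Aboriginality weight-of-evidence algorithm and the Multi-stage median),
    and evaluates each rule's record-level accuracy (sensitivity,
    specificity, PPV, NPV, F score) against a self-reported reference
    standard, stratified by data source and age group. Includes a synthetic
    linked-cohort generator calibrated to the structure of the NSW Patient
    Survey Program linkage study, so the whole workflow is reproducible
    without access to confidential linked data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
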