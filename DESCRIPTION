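Package: rorscreen
Title: Disproportionality Screening of Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A signal-detection pipeline for spontaneous adverse-event
    report databases in the style of the FDA Adverse Event Reporting
    System (FAERS). Parses quarterly "$"-delimited DEMO/DRUG/REAC files,
    normalizes verbatim drug names against a synonym dictionary, maps
    MedDRA preferred terms to a composite event definition with
    histological subtypes, deduplicates case versions, and screens drugs
    for disproportionate reporting using the reporting odds ratio (ROR)
    with Woolf confidence intervals and z-test p-values. Includes
    stratified screens, demographic summaries, yearly trend counts,
    subtype breakdowns, and a seeded synthetic report generator with
    known ground truth for validation without a database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
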