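Package: polyrx
Title: Quantifying Polypharmacy from Prescription Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying concomitant multi-drug exposure
    (polypharmacy) from outpatient prescription claims. Prescriptions are
    scanned into discrete, non-overlapping exposure windows of patient age;
    per-window drug sets are summarized into exact and "at-least"
    combination exposure counts for up to five drug ingredients or ATC
    level-2 classes, with Apriori-style candidate generation, observed
    versus expected overrepresentation ratios, and daily-cost estimates.
    Includes a synthetic claims-cohort simulator with planted
    co-prescription structure for validating every pipeline stage against
    known ground truth, emitters and readers for the tab-delimited
    publication record formats, co-drug exposure profiling, outcome
    relative-risk screening, and window-duration and cohort-size
    sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
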