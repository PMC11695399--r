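Package: pvsignal
Title: Disproportionality Analysis of Spontaneous Adverse-Event Reports
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pharmacovigilance signal detection on spontaneous
    adverse-event report databases in the FAERS quarterly-extract style.
    Builds 2x2 drug-event contingency tables against the all-other-reports
    comparator, computes the reporting odds ratio with Woolf confidence
    intervals, the Yates-corrected chi-squared statistic, the standard
    three-part signal rule (lbROR > 1, chi-squared > 4, n > 3), Jeffreys
    binomial rate intervals, Fisher's exact test, sex-stratified reporting
    odds ratios with a closed-form drug-by-sex interaction test, and yearly
    reporting trends. Includes a synthetic report-database generator with
    planted associations for validation, and the published
    hydroxychloroquine-pemphigus contingency counts as a built-in fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
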