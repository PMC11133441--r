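Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FDA Adverse Event
    Reporting System (FAERS) quarterly ASCII extracts. Reads and writes the
    dollar-delimited DEMO/DRUG/REAC/OUTC/INDI/THER/RPSR tables, applies the
    FDA-recommended case deduplication (latest FDA receipt date, ties broken by
    report-version identifier), extracts a primary-suspect drug cohort, builds
    descriptive frequency tables (demographics, severe outcomes, preferred-term
    and system-organ-class frequencies, annual report counts), and detects
    adverse-event signals from per-term 2x2 contingency tables via the
    reporting odds ratio (ROR, with Woolf-type 95% confidence interval) and the
    proportional reporting ratio (PRR, with Pearson chi-squared), using the
    conventional thresholds (a >= 3 with ROR CI lower bound > 1; a >= 3 with
    PRR > 2 and chi-squared > 4). A synthetic-data generator produces
    FAERS-like multi-table datasets with planted drug-event signals so the full
    pipeline can be exercised and validated without access to FAERS itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
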