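Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style quarterly report tables. Reads '$'-delimited DEMO, DRUG,
    REAC, OUTC and THER quarterly extracts, applies hierarchical case
    deduplication and deletion-list removal, codes reactions to MedDRA
    preferred terms and system organ classes through a user-supplied
    mapping, and screens drug-event pairs with four disproportionality
    estimators: the reporting odds ratio, the proportional reporting ratio
    with the MHRA composite criterion, the BCPNN information component and
    the multi-item gamma-Poisson shrinker (EBGM). Also models time-to-onset
    with a Weibull distribution and produces descriptive characteristics
    tables. A configurable synthetic-report generator with planted
    reporting-rate ratios makes every stage testable without access to the
    real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    optparse
Config/testthat/edition: 3
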