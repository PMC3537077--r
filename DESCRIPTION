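Package: tseca
Title: Trial Similarity and Evidence Consistency Assessment for Indirect
    Treatment Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for adjusted indirect treatment comparisons of binary
    outcomes via a common comparator (the Bucher method), quantification of
    the discrepancy between direct and indirect estimates as a ratio of odds
    ratios with a z-test for inconsistency, aggregation rules for structured
    Trial Similarity / Quality Similarity / Evidence Consistency Assessment
    (TSECA) scores, Bland-Altman interassessor agreement, quantile-subgroup
    association analyses, and a simulator of three-set evidence networks
    with known ground truth for calibration and operating-characteristic
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
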