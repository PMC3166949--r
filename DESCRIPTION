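Package: pkaglc
Title: PKA Dependence of the Yeast Transcriptional Response to Glucose
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for classifying Saccharomyces cerevisiae genes
    by the dependence of their glucose response on protein kinase A (PKA).
    Reads probe-set expression matrices (tab-delimited or GEO Series Matrix),
    performs global per-array scaling to a target mean signal, computes
    induction and repression factors with a rule-based response taxonomy
    (total / partial / none, four PKA-dependence classes, transient versus
    sustained dynamics, gluconeogenic PKA requirement), implements the SAM
    permutation statistic for very small replicate numbers, and ships a
    synthetic-data generator with planted regulatory classes plus recovery
    scoring for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
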