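Package: splicescreen
Title: Pooled shRNA Screen Analysis and AML Cohort Scoring for Splicing-Factor Tumor Suppressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of pooled in vivo shRNA dropout/enrichment screens with a
    counter-screen filter, and downstream scoring of patient expression cohorts.
    Implements hairpin counting from barcoded amplicon reads, total-read and
    control-shRNA fold-change normalization, percentile-rank gene-level hit
    calling, transcript-isoform set scores (BCL2L1 L/S ratio, BIN1 exon-12
    inclusion), reference-gene-normalized signature scoring, Kaplan-Meier and
    log-rank survival stratification, and negative-binomial simulators that
    generate screens and cohorts with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
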