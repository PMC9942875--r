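Package: bescan
Title: Base-Editing Mutagenesis Screen Design, Scoring and Genotype Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for CRISPR base-editing mutagenesis screens: tiling
    guide-RNA library design over gene models with editor-specific
    editability profiling, prediction of edited alleles and their protein
    consequences under cytidine or adenine editor models, screen enrichment
    statistics (reads-per-million normalization, log2 fold changes,
    empirical-Bayes z-scores with element-level aggregation and
    loss-/gain-/separation-of-function classification), genotype
    verification from amplicon variant tables and single-cell guide-UMI
    matrices (skew-t mixture guide assignment, ploidy-aware zygosity and
    consensus-edit calling, false-negative-rate estimation), and seeded
    synthetic-data generators that emulate the statistical structure of
    each input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
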