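Package: exomody
Title: Exome-Based Rare-Variant Diagnostics for Monogenic Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exome-based molecular diagnostics of maturity-onset
    diabetes of the young (MODY) and related monogenic diabetes. Implements
    site-level variant quality control (depth, quality and SNP-cluster
    filters), coding-consequence annotation with simplified HGVS c./p.
    naming, a rare-variant reduction cascade (coding filter, in-house
    exome-database exclusion, population allele-frequency filter,
    candidate-gene-panel intersection) with per-stage accounting,
    capture-target coverage audits, sequencing-versus-array heterozygous
    genotype concordance, and rule-based pathogenicity triage from
    in-silico predictor verdicts, control-cohort frequencies and family
    segregation. A seeded simulator generates complete synthetic exome
    cohorts (reference, gene models, capture targets, per-sample variant
    sets, depth tracks and array genotypes) calibrated to published
    diagnostic-exome magnitudes, including spike-in pathogenic variants
    for recall testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
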