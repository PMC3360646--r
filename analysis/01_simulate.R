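#!/usr/bin/env Rscript
# Build the synthetic study: a toy exome (reference, gene models, capture
# targets, candidate panel) and a nine-proband cohort calibrated to the
# diagnostic-exome magnitudes the package models (on average ~14,463 exonic
# variants per sample, ~6,633 coding, ~253 after in-house exclusion, ~199
# rare), at 1/10 scale so the whole analysis folder runs in about a minute.
# Writes standard-format inputs under results/simulated/.
#
# Every downstream driver regenerates the same objects from the same seed,
# so no binary intermediates are needed.

suppressMessages(library(exomody))

SEED <- 20120525L
params <- sim_params(scale = 0.1, n_genes = 60)

assets <- generate_reference_and_genes(params, seed = SEED)
cohort <- generate_cohort(params, assets, seed = SEED + 1L)
cohort <- spike_pathogenic(cohort, assets, k = 3L, seed = SEED + 2L)

out <- "results/simulated"
paths <- suppressWarnings(write_assets(assets, out))
vcfs <- write_cohort_vcfs(cohort, file.path(out, "vcf"))
utils::write.table(cohort$annotations, file.path(out, "annotations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("Toy genome: ", length(assets$models$transcripts), " genes over ",
        length(assets$ref), " chromosomes; capture targets ",
        sum(GenomicRanges::width(assets$targets)), " bp; panel genes absent ",
        "from capture (by design): ",
        paste(assets$absent_genes, collapse = ", "))
message("Cohort: ", length(cohort$samples), " samples, ",
        nrow(cohort$calls), " calls; ", nrow(cohort$truth),
        " spiked pathogenic variants (",
        paste(cohort$truth$gene, collapse = ", "), ")")
message("Inputs written under ", out)
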