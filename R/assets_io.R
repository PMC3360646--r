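# Writers for generated assets: FASTA reference, GFF3 and TSV gene models,
# BED capture targets, panel TSV, per-sample cohort VCFs and a JSON run
# manifest.

#' Write gene models in the simplified TSV dialect
#'
#' One row per transcript: `transcript_id, gene, chrom, strand,
#' exon_starts, exon_ends, cds_start, cds_end`; exon bounds comma-separated,
#' all coordinates 1-based inclusive.
#'
#' @param models An `exomody_models` collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_tsv <- function(models, path) {
  rows <- lapply(models$transcripts, function(t) {
    data.frame(transcript_id = t$transcript_id, gene = t$gene,
               chrom = t$chrom, strand = t$strand,
               exon_starts = paste(t$exon_starts + 1L, collapse = ","),
               exon_ends = paste(t$exon_ends, collapse = ","),
               cds_start = t$cds_start + 1L, cds_end = t$cds_end,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS features with `ID`/`Parent` links, readable by
#' [load_gene_models()].
#'
#' @param models An `exomody_models` collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  feats <- lapply(models$transcripts, function(t) {
    gid <- paste0("gene:", t$gene)
    n_ex <- length(t$exon_starts)
    gr <- GenomicRanges::GRanges(
      seqnames = t$chrom,
      ranges = IRanges::IRanges(
        start = c(t$exon_starts[1] + 1L, t$exon_starts[1] + 1L,
                  t$exon_starts + 1L, t$cds_exon_starts + 1L),
        end = c(t$exon_ends[n_ex], t$exon_ends[n_ex],
                t$exon_ends, t$cds_exon_ends)),
      strand = t$strand)
    n_cds <- length(t$cds_exon_starts)
    S4Vectors::mcols(gr)$type <- c("gene", "mRNA", rep("exon", n_ex),
                                   rep("CDS", n_cds))
    S4Vectors::mcols(gr)$ID <- c(gid, t$transcript_id,
                                 paste0(t$transcript_id, ":exon", seq_len(n_ex)),
                                 paste0(t$transcript_id, ":cds", seq_len(n_cds)))
    S4Vectors::mcols(gr)$Parent <- c(NA, gid,
                                     rep(t$transcript_id, n_ex + n_cds))
    # phase of each CDS piece in transcription order
    w <- t$cds_exon_ends - t$cds_exon_starts
    ord <- if (t$strand == "+") seq_along(w) else rev(seq_along(w))
    ph <- integer(length(w))
    ph[ord] <- (3L - cumsum(c(0L, w[ord]))[seq_along(w)] %% 3L) %% 3L
    S4Vectors::mcols(gr)$phase <- c(rep(NA_integer_, 2L + n_ex), ph)
    S4Vectors::mcols(gr)$gene_name <- t$gene
    gr
  })
  gff <- suppressWarnings(do.call(c, unname(feats)))
  rtracklayer::export(gff, path, format = "gff3")
  invisible(path)
}

#' Write all simulation assets to a directory
#'
#' @param assets A `sim_assets` bundle ([generate_reference_and_genes()]).
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (`fasta`, `gff3`, `gene_models_tsv`,
#'   `bed`, `panel`).
#' @export
write_assets <- function(assets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "reference.fa"),
                gff3 = file.path(dir, "genes.gff3"),
                gene_models_tsv = file.path(dir, "genes.tsv"),
                bed = file.path(dir, "capture_targets.bed"),
                panel = file.path(dir, "panel.tsv"))
  Biostrings::writeXStringSet(assets$ref, paths$fasta)
  write_gene_models_gff3(assets$models, paths$gff3)
  write_gene_models_tsv(assets$models, paths$gene_models_tsv)
  rtracklayer::export(assets$targets, paths$bed, format = "bed")
  utils::write.table(assets$panel$entries, paths$panel, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Write a cohort's per-sample VCFs
#'
#' @param cohort A `sim_cohort` ([generate_cohort()]).
#' @param dir Output directory.
#' @return Named character vector of VCF paths, one per sample.
#' @export
write_cohort_vcfs <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$samples, function(s) {
    p <- file.path(dir, paste0(s, ".vcf.gz"))
    write_vcf(cohort$calls[cohort$calls$sample_id == s, , drop = FALSE], p)
    p
  }, "")
  paths
}

#' Write a per-sample depth track as TSV
#'
#' Three columns (`chrom`, `pos`, `depth`), 1-based positions, the layout of
#' a samtools-depth stream with a header line.
#'
#' @param track Depth track `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-base depth track
#'
#' Accepts the package's 3-column TSV (with header) or a headerless
#' samtools-depth stream.
#'
#' @param path TSV file.
#' @return `data.frame` with `chrom`, `pos`, `depth`.
#' @export
read_depth_track <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "pos", "depth")
  df$chrom <- norm_chrom(df$chrom)
  df
}
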