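# Candidate-gene panel handling and capture/coverage accounting: per-gene
# captured fraction (detecting panel genes absent from the capture design),
# region coverage summaries (median depth, fraction of bases at >=8X/20X)
# and per-gene fractions of CDS bases covered at a minimum depth.

#' Construct a gene panel
#'
#' @param entries `data.frame` with columns `gene`, `reason`, `transcript`
#'   (transcript may be NA).
#' @param label Panel label.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(entries, label = "panel") {
  stopifnot(is.data.frame(entries), nrow(entries) > 0L,
            all(c("gene", "reason") %in% names(entries)))
  if (!"transcript" %in% names(entries)) entries$transcript <- NA_character_
  if (anyDuplicated(entries$gene)) {
    stop("duplicate gene symbol(s) in panel: ",
         paste(unique(entries$gene[duplicated(entries$gene)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(entries = entries[, c("gene", "reason", "transcript")],
                 label = label), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene panel '%s': %d genes>\n", x$label, nrow(x$entries)))
  invisible(x)
}

#' Load a gene panel from TSV
#'
#' Expects a header line with columns `gene`, `reason` and optionally
#' `transcript`.
#'
#' @param path TSV file.
#' @param label Panel label (defaults to the file name).
#' @return A [gene_panel()].
#' @export
load_panel <- function(path, label = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty gene panel: ", path, call. = FALSE)
  if (!all(c("gene", "reason") %in% names(df))) {
    stop("panel TSV must have 'gene' and 'reason' columns", call. = FALSE)
  }
  gene_panel(df, label = label %||% basename(path))
}

#' Default monogenic-diabetes candidate panel
#'
#' The genes named in the diagnostic literature this package models: the
#' classical MODY genes, other monogenic/syndromic diabetes genes, beta-cell
#' genes and GWAS-implicated candidates. Full clinical panels should be
#' supplied as TSV via [load_panel()].
#'
#' @return A [gene_panel()] of 25 genes.
#' @export
default_panel <- function() {
  mody <- c("GCK", "HNF1A", "HNF4A", "HNF1B", "INS", "BLK", "CEL", "KLF11",
            "NEUROD1", "PAX4", "PDX1")
  mono <- c("ABCC8", "PPARG", "ALMS1", "HADH", "WFS1", "GLIS3")
  gwas <- c("ARAP1", "CRY2", "MADD", "NOTCH2", "SREBF1", "STARD10",
            "DGKB", "THADA")
  gene_panel(data.frame(
    gene = c(mody, mono, gwas),
    reason = c(rep("known MODY gene", length(mody)),
               rep("monogenic/syndromic diabetes", length(mono)),
               rep("GWAS/beta-cell candidate", length(gwas))),
    transcript = NA_character_,
    stringsAsFactors = FALSE
  ), label = "default-diabetes-panel")
}

#' Genes with established autosomal-dominant diabetes phenotypes
#'
#' Used by triage: a protein-altering, rare, validated variant in one of
#' these genes can be classed pathogenic; variants in other candidates stay
#' "uncertain" pending stronger evidence.
#'
#' @return Character vector of gene symbols.
#' @export
known_dominant_diabetes_genes <- function() {
  c("GCK", "HNF1A", "HNF4A", "HNF1B", "INS", "BLK", "CEL", "KLF11",
    "NEUROD1", "PAX4", "PDX1", "ABCC8", "PPARG")
}

#' Load capture targets from BED
#'
#' @param path BED file (0-based half-open, as standard).
#' @return A [GenomicRanges::GRanges] with normalized chromosome names.
#' @export
load_targets <- function(path) {
  g <- rtracklayer::import(path, format = "bed")
  GenomeInfoDb::seqlevels(g) <- norm_chrom(GenomeInfoDb::seqlevels(g))
  g
}

cds_granges <- function(models, genes = NULL) {
  txs <- models$transcripts
  if (!is.null(genes)) {
    ids <- unlist(models$by_gene[intersect(genes, names(models$by_gene))])
    txs <- txs[ids]
  }
  if (!length(txs)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(lapply(txs, function(t) {
    GenomicRanges::GRanges(t$chrom,
                           IRanges::IRanges(t$cds_exon_starts + 1L, t$cds_exon_ends),
                           gene = t$gene)
  }))))
}

#' Audit panel capture
#'
#' For each panel gene, the fraction of its CDS bases contained in the
#' capture-target intervals. Genes with zero overlap are reported absent
#' from the capture design; panel genes missing from the gene models are
#' listed unmappable (not an error).
#'
#' @param panel A [gene_panel()].
#' @param targets Capture targets (`GRanges` or BED path).
#' @param models Gene models.
#' @return `data.frame` with `gene`, `captured_fraction`, `status`
#'   (`captured` / `absent_from_capture` / `unmappable`).
#' @export
capture_audit <- function(panel, targets, models) {
  if (is.character(targets)) targets <- load_targets(targets)
  targets <- GenomicRanges::reduce(targets)
  out <- lapply(panel$entries$gene, function(g) {
    if (!g %in% names(models$by_gene)) {
      return(data.frame(gene = g, captured_fraction = NA_real_,
                        status = "unmappable", stringsAsFactors = FALSE))
    }
    cds <- GenomicRanges::reduce(cds_granges(models, g))
    tot <- sum(GenomicRanges::width(cds))
    cov <- sum(GenomicRanges::width(GenomicRanges::intersect(cds, targets,
                                                             ignore.strand = TRUE)))
    frac <- cov / tot
    data.frame(gene = g, captured_fraction = frac,
               status = if (cov == 0L) "absent_from_capture" else "captured",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Expand regions to the per-base universe; returns data.frame(chrom, pos)
region_bases <- function(regions) {
  regions <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  data.frame(
    chrom = rep(norm_chrom(as.character(GenomicRanges::seqnames(regions))),
                GenomicRanges::width(regions)),
    pos = unlist(lapply(seq_along(regions), function(i) {
      seq.int(GenomicRanges::start(regions)[i], GenomicRanges::end(regions)[i])
    })),
    stringsAsFactors = FALSE
  )
}

depth_at <- function(track, bases) {
  key <- paste(bases$chrom, bases$pos)
  tkey <- paste(norm_chrom(track$chrom), track$pos)
  d <- track$depth[match(key, tkey)]
  d[is.na(d)] <- 0
  d
}

#' Coverage summary over a region set
#'
#' Median read depth and fractions of bases at or above each threshold,
#' computed over every base of the (merged) regions; bases absent from the
#' depth track count as depth 0. With an even base count the median is the
#' mean of the central pair.
#'
#' @param track Depth track: `data.frame` with `chrom`, `pos` (1-based),
#'   `depth`.
#' @param regions `GRanges` of regions (must be non-empty).
#' @param thresholds Depth thresholds (default `c(8, 20)`).
#' @param label Region-set label.
#' @return One-row `data.frame`: `region_set`, `n_bases`, `median_depth`,
#'   and one `frac_ge_<t>` column per threshold (fractions in `[0,1]`).
#' @export
coverage_summary <- function(track, regions, thresholds = c(8, 20),
                             label = "targets") {
  if (length(regions) == 0L) stop("empty region set", call. = FALSE)
  bases <- region_bases(regions)
  d <- depth_at(track, bases)
  out <- data.frame(region_set = label, n_bases = length(d),
                    median_depth = stats::median(d),
                    stringsAsFactors = FALSE)
  for (t in thresholds) out[[paste0("frac_ge_", t)]] <- mean(d >= t)
  out
}

#' Per-gene CDS coverage
#'
#' Fraction of each panel gene's CDS bases covered at `min_depth` or more.
#' Genes absent from the capture design (per [capture_audit()], when targets
#' are supplied) are reported not assessable.
#'
#' @param track Depth track (`chrom`, `pos`, `depth`).
#' @param models Gene models.
#' @param panel A [gene_panel()].
#' @param targets Optional capture targets for absence flagging.
#' @param min_depth Depth threshold (default 8).
#' @return `data.frame` with `gene`, `n_cds_bases`, `frac_covered`, `status`.
#' @export
per_gene_coverage <- function(track, models, panel, targets = NULL,
                              min_depth = 8) {
  audit <- if (!is.null(targets)) capture_audit(panel, targets, models) else NULL
  out <- lapply(panel$entries$gene, function(g) {
    status <- if (!is.null(audit)) audit$status[audit$gene == g] else "captured"
    if (!g %in% names(models$by_gene) || status != "captured") {
      return(data.frame(gene = g, n_cds_bases = NA_integer_,
                        frac_covered = NA_real_,
                        status = if (g %in% names(models$by_gene)) "not_assessable" else "unmappable",
                        stringsAsFactors = FALSE))
    }
    bases <- region_bases(cds_granges(models, g))
    d <- depth_at(track, bases)
    data.frame(gene = g, n_cds_bases = nrow(bases),
               frac_covered = mean(d >= min_depth), status = "captured",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
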