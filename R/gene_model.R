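# Gene-model storage and genomic <-> coding-DNA coordinate arithmetic.
#
# Internal convention: all interval coordinates are 0-based half-open.
# External formats are converted at the I/O boundary (GFF3 and the TSV
# dialect are 1-based inclusive; BED is already 0-based half-open).

#' Construct a transcript model
#'
#' @param transcript_id,gene Identifiers.
#' @param chrom Chromosome name (normalized on construction).
#' @param strand "+" or "-".
#' @param exon_starts,exon_ends Integer vectors of exon bounds, 0-based
#'   half-open, in genomic order.
#' @param cds_start,cds_end CDS span, 0-based half-open genomic.
#' @return An object of class `exomody_transcript`.
#' @details Exons must be sorted and non-overlapping; the CDS must lie inside
#'   the exon union. A CDS whose length is not a multiple of 3 is accepted
#'   with a warning and flagged (`cds_frame_warning`), and is skipped by the
#'   consequence classifier.
#' @export
new_transcript <- function(transcript_id, gene, chrom, strand,
                           exon_starts, exon_ends, cds_start, cds_end) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1L)
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (any(exon_ends <= exon_starts)) {
    stop("transcript ", transcript_id, ": empty or inverted exon", call. = FALSE)
  }
  ord <- order(exon_starts)
  exon_starts <- exon_starts[ord]; exon_ends <- exon_ends[ord]
  n <- length(exon_starts)
  if (n > 1L && any(exon_starts[-1L] < exon_ends[-n])) {
    stop("transcript ", transcript_id, ": overlapping exons", call. = FALSE)
  }
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_end <= cds_start) {
    stop("transcript ", transcript_id, ": empty CDS", call. = FALSE)
  }
  # CDS exon pieces (genomic order)
  cs <- pmax(exon_starts, cds_start)
  ce <- pmin(exon_ends, cds_end)
  keep <- ce > cs
  cds_exon_starts <- cs[keep]; cds_exon_ends <- ce[keep]
  cds_len <- sum(cds_exon_ends - cds_exon_starts)
  # CDS must be fully contained in the exon union: both CDS endpoints have
  # to fall inside an exon (gaps between sorted exons are introns)
  if (!any(exon_starts <= cds_start & cds_start < exon_ends) ||
      !any(exon_starts < cds_end & cds_end <= exon_ends)) {
    stop("transcript ", transcript_id, ": CDS extends outside exons", call. = FALSE)
  }
  frame_warn <- (cds_len %% 3L) != 0L
  if (frame_warn) {
    warning("transcript ", transcript_id, ": CDS length ", cds_len,
            " is not a multiple of 3", call. = FALSE)
  }
  structure(list(
    transcript_id = as.character(transcript_id),
    gene = as.character(gene),
    chrom = norm_chrom(chrom),
    strand = match.arg(strand, c("+", "-")),
    exon_starts = exon_starts, exon_ends = exon_ends,
    cds_start = cds_start, cds_end = cds_end,
    cds_exon_starts = cds_exon_starts, cds_exon_ends = cds_exon_ends,
    cds_len = cds_len,
    cds_frame_warning = frame_warn
  ), class = "exomody_transcript")
}

#' @export
print.exomody_transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d [%s] %d exons, CDS %d bp>\n",
              x$transcript_id, x$gene, x$chrom,
              x$exon_starts[1] + 1L, x$exon_ends[length(x$exon_ends)],
              x$strand, length(x$exon_starts), x$cds_len))
  invisible(x)
}

#' Bundle transcripts into a gene-model collection
#'
#' @param transcripts List of `exomody_transcript` objects.
#' @return An object of class `exomody_models`, indexed by transcript id and
#'   by gene symbol, with a [GenomicRanges::GRanges] of transcript spans for
#'   interval queries.
#' @export
gene_models <- function(transcripts) {
  stopifnot(length(transcripts) >= 1L)
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids", call. = FALSE)
  names(transcripts) <- ids
  genes <- vapply(transcripts, `[[`, "", "gene")
  spans <- GenomicRanges::GRanges(
    seqnames = vapply(transcripts, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(transcripts, function(t) t$exon_starts[1] + 1L, 1L),
      end = vapply(transcripts, function(t) t$exon_ends[length(t$exon_ends)], 1L)
    ),
    transcript_id = ids
  )
  structure(list(
    transcripts = transcripts,
    by_gene = split(ids, genes),
    spans = spans
  ), class = "exomody_models")
}

#' @export
print.exomody_models <- function(x, ...) {
  cat(sprintf("<gene models: %d transcripts, %d genes>\n",
              length(x$transcripts), length(x$by_gene)))
  invisible(x)
}

#' Look up transcripts overlapping a position
#'
#' @param models An `exomody_models` collection.
#' @param chrom,pos 1-based genomic position.
#' @param pad Extra flanking bases to include (e.g. splice window).
#' @return List of transcripts (possibly empty).
#' @export
transcripts_at <- function(models, chrom, pos, pad = 0L) {
  q <- GenomicRanges::GRanges(norm_chrom(chrom),
                              IRanges::IRanges(pos - pad, pos + pad))
  hits <- GenomicRanges::findOverlaps(q, models$spans)
  models$transcripts[S4Vectors::subjectHits(hits)]
}

# Internal: pick the annotation transcript among overlaps (longest CDS)
pick_transcript <- function(txs) {
  if (length(txs) == 0L) return(NULL)
  lens <- vapply(txs, `[[`, 1L, "cds_len")
  txs[[order(-lens, vapply(txs, `[[`, "", "transcript_id"))[1L]]]
}

#' Load gene models from GFF3 or the simplified TSV dialect
#'
#' The TSV dialect has one row per transcript with columns
#' `transcript_id, gene, chrom, strand, exon_starts, exon_ends, cds_start,
#' cds_end`; exon bounds are comma-separated 1-based inclusive coordinates.
#' GFF3 must carry gene/mRNA/exon/CDS features with `ID`/`Parent` links.
#'
#' @param path File path.
#' @param format "auto" (by extension), "gff3" or "tsv".
#' @return An `exomody_models` collection.
#' @export
load_gene_models <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") load_gene_models_gff3(path) else load_gene_models_tsv(path)
}

load_gene_models_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene", "chrom", "strand",
            "exon_starts", "exon_ends", "cds_start", "cds_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gene-model TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  txs <- lapply(seq_len(nrow(df)), function(i) {
    es <- suppressWarnings(as.integer(strsplit(df$exon_starts[i], ",")[[1]]))
    ee <- suppressWarnings(as.integer(strsplit(df$exon_ends[i], ",")[[1]]))
    if (anyNA(es) || anyNA(ee) || length(es) != length(ee)) {
      stop("malformed exon blocks at line ", i + 1L, " of ", path, call. = FALSE)
    }
    new_transcript(df$transcript_id[i], df$gene[i], df$chrom[i], df$strand[i],
                   es - 1L, ee, df$cds_start[i] - 1L, df$cds_end[i])
  })
  gene_models(txs)
}

load_gene_models_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(g)
  type <- as.character(meta$type)
  get_attr <- function(idx, field) {
    if (!field %in% names(meta)) return(NA_character_)
    v <- meta[[field]][idx]
    if (is.list(v)) v <- vapply(v, function(e) if (length(e)) e[[1]] else NA_character_, "")
    as.character(v)
  }
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  if (!length(mrna_idx)) stop("no mRNA/transcript features in ", path, call. = FALSE)
  parent_of <- function(idx) {
    p <- meta$Parent[idx]
    vapply(p, function(e) if (length(e)) as.character(e[[1]]) else NA_character_, "")
  }
  exon_idx <- which(type == "exon")
  cds_idx <- which(type == "CDS")
  exon_parent <- parent_of(exon_idx)
  cds_parent <- parent_of(cds_idx)
  txs <- lapply(mrna_idx, function(i) {
    tid <- get_attr(i, "ID")
    gene <- get_attr(i, "gene_name")
    if (is.na(gene)) gene <- get_attr(i, "gene")
    if (is.na(gene)) gene <- get_attr(i, "Name")
    if (is.na(gene)) gene <- tid
    ex <- exon_idx[exon_parent == tid]
    cd <- cds_idx[cds_parent == tid]
    if (!length(ex)) stop("transcript ", tid, " has no exon features", call. = FALSE)
    if (!length(cd)) stop("transcript ", tid, " has no CDS features", call. = FALSE)
    new_transcript(
      tid, gene,
      as.character(GenomicRanges::seqnames(g))[i],
      as.character(GenomicRanges::strand(g))[i],
      GenomicRanges::start(g)[ex] - 1L, GenomicRanges::end(g)[ex],
      min(GenomicRanges::start(g)[cd]) - 1L, max(GenomicRanges::end(g)[cd])
    )
  })
  gene_models(txs)
}

#' Map a genomic position onto transcript coordinates
#'
#' @param tx An `exomody_transcript`.
#' @param pos 1-based genomic position on the transcript's chromosome.
#' @return A list with elements:
#'   * `kind`: one of `"cds"`, `"intronic"`, `"noncoding_exonic"`, `"outside"`;
#'   * `cds_pos`: 1-based coding-DNA (c.) position for `kind == "cds"`;
#'   * `offset`: for intronic positions, the signed HGVS-style distance to the
#'     nearest exon edge in transcription orientation (+1 is the first base of
#'     an intron after a donor site);
#'   * `anchor_cds`: for intronic positions, the c. position of the flanking
#'     exonic base (NA when that base is non-coding).
#' @export
cds_coordinate <- function(tx, pos) {
  p0 <- as.integer(pos) - 1L
  n <- length(tx$exon_starts)
  if (p0 < tx$exon_starts[1L] || p0 >= tx$exon_ends[n]) {
    return(list(kind = "outside", cds_pos = NA_integer_,
                offset = NA_integer_, anchor_cds = NA_integer_))
  }
  in_exon <- which(tx$exon_starts <= p0 & p0 < tx$exon_ends)
  if (length(in_exon)) {
    if (p0 >= tx$cds_start && p0 < tx$cds_end) {
      cs <- tx$cds_exon_starts; ce <- tx$cds_exon_ends
      if (tx$strand == "+") {
        cpos <- sum(pmax(0L, pmin(p0, ce) - cs)) + 1L
      } else {
        cpos <- sum(pmax(0L, ce - pmax(p0 + 1L, cs))) + 1L
      }
      return(list(kind = "cds", cds_pos = as.integer(cpos),
                  offset = NA_integer_, anchor_cds = NA_integer_))
    }
    return(list(kind = "noncoding_exonic", cds_pos = NA_integer_,
                offset = NA_integer_, anchor_cds = NA_integer_))
  }
  # intronic: distance to flanking exon edges
  left <- max(which(tx$exon_ends <= p0))     # exon genomically before
  d_left <- p0 - tx$exon_ends[left] + 1L     # bases into intron from left exon
  d_right <- tx$exon_starts[left + 1L] - p0  # bases before right exon
  anchor_left <- tx$exon_ends[left]          # 1-based pos of left exon last base
  anchor_right <- tx$exon_starts[left + 1L] + 1L
  if (tx$strand == "+") {
    use_left <- d_left <= d_right            # donor side wins ties
    offset <- if (use_left) d_left else -d_right
    anchor <- if (use_left) anchor_left else anchor_right
  } else {
    use_right <- d_right <= d_left           # donor side is the genomic-right exon
    offset <- if (use_right) d_right else -d_left
    anchor <- if (use_right) anchor_right else anchor_left
  }
  aloc <- cds_coordinate(tx, anchor)
  list(kind = "intronic", cds_pos = NA_integer_, offset = as.integer(offset),
       anchor_cds = if (aloc$kind == "cds") aloc$cds_pos else NA_integer_)
}

#' Inverse of [cds_coordinate()]: genomic position of a c. coordinate
#'
#' @param tx An `exomody_transcript`.
#' @param cds_pos 1-based coding-DNA position.
#' @return 1-based genomic position.
#' @export
genomic_coordinate <- function(tx, cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L || cds_pos > tx$cds_len) {
    stop("cds position ", cds_pos, " outside CDS of length ", tx$cds_len,
         call. = FALSE)
  }
  cs <- tx$cds_exon_starts; ce <- tx$cds_exon_ends
  w <- ce - cs
  if (tx$strand == "+") {
    cum <- cumsum(w); i <- which(cds_pos <= cum)[1L]
    offset_in <- cds_pos - c(0L, cum)[i] - 1L
    cs[i] + offset_in + 1L
  } else {
    w_rev <- rev(w); cum <- cumsum(w_rev)
    i_rev <- which(cds_pos <= cum)[1L]
    i <- length(w) - i_rev + 1L
    offset_in <- cds_pos - c(0L, cum)[i_rev] - 1L
    ce[i] - offset_in
  }
}

#' Spliced CDS sequence of a transcript
#'
#' @param tx An `exomody_transcript`.
#' @param ref Reference (see [load_reference()]).
#' @return Character string: the CDS read 5'->3' on the coding strand.
#' @export
cds_sequence <- function(tx, ref) {
  chunks <- mapply(function(s, e) ref_bases(ref, tx$chrom, s + 1L, e),
                   tx$cds_exon_starts, tx$cds_exon_ends)
  s <- paste(chunks, collapse = "")
  if (tx$strand == "-") dna_revcomp(s) else s
}

#' Codon context of a coding-DNA position
#'
#' @param tx An `exomody_transcript`.
#' @param cds_pos 1-based coding-DNA position.
#' @param ref Reference sequence set.
#' @return List with `codon_index` (1-based), `codon_bases` (3-mer on the
#'   coding strand) and `offset_within_codon` (1, 2 or 3).
#' @export
codon_context <- function(tx, cds_pos, ref) {
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L || cds_pos > tx$cds_len) {
    stop("cds position out of range: ", cds_pos, call. = FALSE)
  }
  ci <- ceiling(cds_pos / 3)
  off <- cds_pos - 3L * (ci - 1L)
  seq <- cds_sequence(tx, ref)
  list(codon_index = as.integer(ci),
       codon_bases = substr(seq, 3L * ci - 2L, 3L * ci),
       offset_within_codon = as.integer(off))
}
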