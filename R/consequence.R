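# Coding-consequence classification and simplified HGVS c./p. naming.
#
# Categories, by precedence: splice_site > coding classes (missense,
# stop_gain, stop_loss, synonymous, frameshift_indel, inframe_indel) >
# noncoding_exonic > intronic > intergenic. Splice sites are the +-2
# intronic bases flanking each exon (the GT/AG dinucleotides); the window is
# configurable. Substitutions are translated with the standard genetic code
# on the coding strand; stop is written "X" in protein names.

consequence_categories <- c("intergenic", "intronic", "splice_site",
                            "noncoding_exonic", "synonymous", "missense",
                            "stop_gain", "stop_loss", "frameshift_indel",
                            "inframe_indel")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Classify the coding consequence of one variant
#'
#' @param chrom,pos,ref_allele,alt_allele The variant (pos 1-based; alleles
#'   on the reference strand, normalized).
#' @param models Gene models ([gene_models()]).
#' @param ref Reference sequence set ([load_reference()]).
#' @param splice_window Intronic bases next to each exon treated as splice
#'   site (default 2, the canonical GT/AG positions).
#' @param check_ref Verify `ref_allele` against the reference (error on
#'   mismatch).
#' @return A one-row `data.frame`: `gene`, `transcript_id`, `category`,
#'   `c_name`, `p_name`, `at_exon_boundary` (TRUE when the variant sits on
#'   the first or last coding base of an internal exon, i.e. immediately
#'   adjacent to a canonical splice site).
#' @export
classify_variant <- function(chrom, pos, ref_allele, alt_allele, models, ref,
                             splice_window = 2L, check_ref = TRUE) {
  res <- function(gene = NA_character_, tid = NA_character_, category,
                  c_name = "", p_name = "", boundary = FALSE) {
    data.frame(gene = gene, transcript_id = tid, category = category,
               c_name = c_name, p_name = p_name, at_exon_boundary = boundary,
               stringsAsFactors = FALSE)
  }
  chrom <- norm_chrom(chrom)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (check_ref && chrom %in% names(ref)) {
    obs <- ref_bases(ref, chrom, pos, pos + nchar(ref_allele) - 1L)
    if (obs != ref_allele) {
      stop("reference mismatch at ", chrom, ":", pos, " (call has ",
           ref_allele, ", reference has ", obs, ")", call. = FALSE)
    }
  }
  txs <- transcripts_at(models, chrom, pos)
  tx <- pick_transcript(txs)
  if (is.null(tx)) return(res(category = "intergenic"))
  if (tx$cds_frame_warning) {
    warning("transcript ", tx$transcript_id,
            " has out-of-frame CDS; classification skipped", call. = FALSE)
    return(res(tx$gene, tx$transcript_id, category = "noncoding_exonic"))
  }
  loc <- cds_coordinate(tx, pos)
  is_snv <- nchar(ref_allele) == 1L && nchar(alt_allele) == 1L
  cod_ref <- if (tx$strand == "+") ref_allele else dna_revcomp(ref_allele)
  cod_alt <- if (tx$strand == "+") alt_allele else dna_revcomp(alt_allele)

  if (loc$kind == "outside") return(res(category = "intergenic"))

  if (loc$kind == "intronic") {
    if (abs(loc$offset) <= splice_window) {
      cn <- if (!is.na(loc$anchor_cds)) {
        sprintf("c.%d%+d%s>%s", loc$anchor_cds, loc$offset, cod_ref, cod_alt)
      } else ""
      return(res(tx$gene, tx$transcript_id, "splice_site", c_name = cn))
    }
    return(res(tx$gene, tx$transcript_id, "intronic"))
  }

  if (loc$kind == "noncoding_exonic") {
    return(res(tx$gene, tx$transcript_id, "noncoding_exonic"))
  }

  # coding
  cpos <- loc$cds_pos
  boundary <- at_coding_exon_boundary(tx, pos)
  if (!is_snv) {
    len_diff <- nchar(alt_allele) - nchar(ref_allele)
    category <- if (len_diff %% 3L != 0L) "frameshift_indel" else "inframe_indel"
    cn <- sprintf("c.%d%s>%s", cpos, cod_ref, cod_alt)
    return(res(tx$gene, tx$transcript_id, category, c_name = cn,
               boundary = boundary))
  }
  ctx <- codon_context(tx, cpos, ref)
  codon <- ctx$codon_bases
  if (substr(codon, ctx$offset_within_codon, ctx$offset_within_codon) != cod_ref) {
    stop("internal inconsistency: coding-strand reference base at c.", cpos,
         " of ", tx$transcript_id, " does not match reference sequence",
         call. = FALSE)
  }
  alt_codon <- codon
  substr(alt_codon, ctx$offset_within_codon, ctx$offset_within_codon) <- cod_alt
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  category <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gain"
    else if (aa_ref == "*") "stop_loss"
    else "missense"
  cn <- sprintf("c.%d%s>%s", cpos, cod_ref, cod_alt)
  pn <- sprintf("p.%s%d%s",
                if (aa_ref == "*") "X" else aa_ref,
                ctx$codon_index,
                if (aa_alt == "*") "X" else aa_alt)
  res(tx$gene, tx$transcript_id, category, c_name = cn, p_name = pn,
      boundary = boundary)
}

# Is this 1-based coding position the first or last coding base of an exon
# that has an adjacent intron on that side?
at_coding_exon_boundary <- function(tx, pos) {
  p0 <- pos - 1L
  i <- which(tx$exon_starts <= p0 & p0 < tx$exon_ends)
  if (!length(i)) return(FALSE)
  n <- length(tx$exon_starts)
  (p0 == tx$exon_starts[i] && i > 1L) || (p0 == tx$exon_ends[i] - 1L && i < n)
}

#' Annotate a table of variant calls
#'
#' Classifies each distinct (chrom, pos, ref, alt) once and returns one
#' annotation row per distinct variant.
#'
#' @param calls Variant-call `data.frame`.
#' @inheritParams classify_variant
#' @return `data.frame` with `chrom`, `pos`, `ref`, `alt` plus the
#'   [classify_variant()] columns.
#' @export
annotate_variants <- function(calls, models, ref, splice_window = 2L,
                              check_ref = TRUE) {
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  u <- !duplicated(key)
  uc <- calls[u, , drop = FALSE]
  ann <- do.call(rbind, lapply(seq_len(nrow(uc)), function(i) {
    classify_variant(uc$chrom[i], uc$pos[i], uc$ref[i], uc$alt[i],
                     models, ref, splice_window, check_ref)
  }))
  cbind(uc[, c("chrom", "pos", "ref", "alt")], ann)
}

#' Does a consequence survive the coding-filter stage?
#'
#' Keeps protein-altering classes and splice-site variants; synonymous
#' changes are kept only when they fall on the first/last coding base of an
#' exon next to a canonical splice site. Non-coding exonic, intronic and
#' intergenic variants are dropped.
#'
#' @param category Consequence category vector.
#' @param at_exon_boundary Logical vector (see [classify_variant()]).
#' @param keep_boundary_synonymous Retain exon-boundary synonymous changes
#'   as splice-relevant (default TRUE).
#' @return Logical vector.
#' @export
is_reduction_coding <- function(category, at_exon_boundary = FALSE,
                                keep_boundary_synonymous = TRUE) {
  at_exon_boundary <- rep_len(at_exon_boundary, length(category))
  category %in% c("missense", "stop_gain", "stop_loss",
                  "frameshift_indel", "inframe_indel", "splice_site") |
    (keep_boundary_synonymous & category == "synonymous" & at_exon_boundary)
}
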