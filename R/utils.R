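# Shared low-level helpers: chromosome-name normalization, allele keys,
# reverse complement, reference lookups.

#' Normalize chromosome names
#'
#' Strips a leading "chr" (any case) and upper-cases the remainder so that
#' mixed-source inputs ("chr1", "Chr1", "1") compare equal.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
norm_chrom <- function(x) {
  toupper(sub("^chr", "", as.character(x), ignore.case = TRUE))
}

#' Canonical allele key
#'
#' One string per normalized allele observation, used for in-house-database
#' membership and frequency-resource lookups (exact-allele matching).
#'
#' @param chrom,pos,ref,alt Vectors describing variants (pos 1-based).
#' @return Character vector "chrom:pos:ref:alt".
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), as.integer(pos), ref, alt, sep = ":")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out[!ok] <- x[!ok]
  out
}

comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Load a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with normalized chromosome names.
#' @export
load_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the sequence name
  names(ref) <- norm_chrom(sub("\\s.*$", "", names(ref)))
  ref
}

#' Reference bases at a genomic window
#'
#' @param ref A `DNAStringSet` (see [load_reference()]) or named character
#'   vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return Character string of bases.
#' @export
ref_bases <- function(ref, chrom, start, end = start) {
  chrom <- norm_chrom(chrom)
  if (!chrom %in% names(ref)) {
    stop("chromosome '", chrom, "' not found in reference", call. = FALSE)
  }
  len <- if (is.character(ref)) nchar(ref[[chrom]]) else length(ref[[chrom]])
  if (start < 1L || end > len || start > end) {
    stop("reference lookup out of bounds: ", chrom, ":", start, "-", end,
         call. = FALSE)
  }
  if (is.character(ref)) {
    substr(ref[[chrom]], start, end)
  } else {
    as.character(Biostrings::subseq(ref[[chrom]], start, end))
  }
}

# Internal: sample random DNA of length n
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a
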