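# Heterozygous genotyping-array vs. sequencing concordance: of the array
# het sites inside the capture regions, what fraction did sequencing also
# call heterozygous?

#' Read array genotypes from TSV
#'
#' Columns: `sample`, `chrom`, `pos` (1-based), `allele_A`, `allele_B`,
#' `call` (`AA`/`AB`/`BB`).
#'
#' @param path TSV file.
#' @return `data.frame` of array genotypes.
#' @export
read_array_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "allele_A", "allele_B", "call")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("array TSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$chrom <- norm_chrom(df$chrom)
  if (anyDuplicated(df[, c("sample", "chrom", "pos")])) {
    stop("duplicate (sample, position) in array genotypes", call. = FALSE)
  }
  df
}

#' Heterozygous-site concordance between array and sequencing
#'
#' Denominator: array heterozygous (AB) sites inside the capture regions.
#' Numerator: those with a heterozygous sequencing call at the same
#' position; in `mode = "allele"` the call's ref/alt pair must additionally
#' equal the array A/B allele pair (a hom-alt call, or a het call with other
#' alleles, counts as not detected). Array sites without usable A/B allele
#' spelling are dropped from the denominator in allele mode (their count is
#' reported).
#'
#' @param array Array genotypes ([read_array_genotypes()] layout).
#' @param calls Sequencing variant-call `data.frame`.
#' @param regions Capture regions (`GRanges`).
#' @param mode `"allele"` (strict, default) or `"position"`.
#' @return `data.frame` with one row per sample: `sample`, `n_array_het`,
#'   `n_detected`, `concordance` (fraction), `n_dropped_unresolved`.
#' @export
het_concordance <- function(array, calls, regions,
                            mode = c("allele", "position")) {
  mode <- match.arg(mode)
  array <- array[array$call == "AB", , drop = FALSE]
  gr <- GenomicRanges::GRanges(norm_chrom(array$chrom),
                               IRanges::IRanges(array$pos, array$pos))
  inside <- IRanges::overlapsAny(gr, regions, ignore.strand = TRUE)
  array <- array[inside, , drop = FALSE]
  n_dropped <- 0L
  if (mode == "allele") {
    ok <- grepl("^[ACGT]$", array$allele_A) & grepl("^[ACGT]$", array$allele_B)
    n_dropped <- sum(!ok)
    if (n_dropped > 0L) {
      message(n_dropped, " array het site(s) with unresolved alleles dropped")
    }
    array <- array[ok, , drop = FALSE]
  }
  if (!nrow(array)) stop("no array het sites inside capture regions", call. = FALSE)
  het <- calls[calls$genotype == "het", , drop = FALSE]
  out <- lapply(sort(unique(array$sample)), function(s) {
    a <- array[array$sample == s, , drop = FALSE]
    if (!nrow(a)) stop("zero denominator for sample ", s, call. = FALSE)
    h <- het[het$sample_id == s, , drop = FALSE]
    pos_key <- paste(a$chrom, a$pos)
    call_key <- paste(h$chrom, h$pos)
    if (mode == "position") {
      det <- pos_key %in% call_key
    } else {
      # unordered allele-pair match
      akey1 <- paste(pos_key, a$allele_A, a$allele_B)
      akey2 <- paste(pos_key, a$allele_B, a$allele_A)
      ckey <- paste(call_key, h$ref, h$alt)
      det <- (akey1 %in% ckey) | (akey2 %in% ckey)
    }
    data.frame(sample = s, n_array_het = nrow(a), n_detected = sum(det),
               concordance = mean(det), n_dropped_unresolved = n_dropped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
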