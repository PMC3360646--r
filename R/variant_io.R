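# VCF ingestion and writing, and allele normalization.
#
# Variant calls travel through the package as a plain data.frame with one
# row per (sample, allele) observation:
#   sample_id, chrom, pos (1-based), ref, alt, qual, depth,
#   genotype ("het"/"hom_alt"), filter ("" = pass, else ";"-joined flags)

variant_call_columns <- c("sample_id", "chrom", "pos", "ref", "alt",
                          "qual", "depth", "genotype", "filter")

#' Assemble a variant-call table
#'
#' @param sample_id,chrom,pos,ref,alt,qual,depth,genotype,filter Column
#'   vectors (recycled to common length where scalar).
#' @return A `data.frame` of variant calls, chromosome names normalized.
#' @export
variant_calls <- function(sample_id, chrom, pos, ref, alt,
                          qual = 100, depth = 30, genotype = "het",
                          filter = "") {
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = norm_chrom(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   qual = as.numeric(qual), depth = as.integer(depth),
                   genotype = as.character(genotype),
                   filter = as.character(filter),
                   stringsAsFactors = FALSE)
  bad <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt)
  if (any(bad)) {
    stop("non-ACGT alleles at row(s) ", paste(head(which(bad)), collapse = ","),
         call. = FALSE)
  }
  if (!all(df$genotype %in% c("het", "hom_alt"))) {
    stop("genotype must be 'het' or 'hom_alt'", call. = FALSE)
  }
  if (any(df$depth < 0L, na.rm = TRUE)) stop("negative depth", call. = FALSE)
  df
}

#' Read a VCF into the package's variant-call table
#'
#' Multi-allelic rows are split into one record per alt allele; genotypes are
#' reduced to het / hom-alt with respect to each alt allele. Records with a
#' missing or hom-ref genotype are skipped (with a warning for missing GT).
#' Depth is taken from the per-sample `DP` FORMAT field when present,
#' otherwise from the site-level `INFO/DP`.
#'
#' @param path VCF file (plain or gzipped).
#' @param samples Optional subset of sample names to keep.
#' @return Variant-call `data.frame` (see [variant_calls()]).
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_mat <- v@gt
  if (is.null(gt_mat) || ncol(gt_mat) < 2L) {
    stop("VCF has no genotype columns: ", path, call. = FALSE)
  }
  all_samples <- colnames(gt_mat)[-1L]
  if (!is.null(samples)) all_samples <- intersect(all_samples, samples)
  info_dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  filt <- fix[, "FILTER"]
  filt[is.na(filt) | filt %in% c(".", "PASS")] <- ""
  out <- vector("list", length(all_samples))
  n_missing_gt <- 0L
  for (si in seq_along(all_samples)) {
    s <- all_samples[si]
    fmt <- gt_mat[, 1L]
    val <- gt_mat[, s]
    rows <- list()
    for (i in seq_len(nrow(fix))) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
      vals <- strsplit(ifelse(is.na(val[i]), ".", val[i]), ":", fixed = TRUE)[[1]]
      gt <- if ("GT" %in% keys) vals[match("GT", keys)] else NA_character_
      if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
        n_missing_gt <- n_missing_gt + 1L
        next
      }
      alleles <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
      if (anyNA(alleles)) { n_missing_gt <- n_missing_gt + 1L; next }
      dp <- if ("DP" %in% keys && length(vals) >= match("DP", keys)) {
        suppressWarnings(as.integer(vals[match("DP", keys)]))
      } else NA_integer_
      if (is.na(dp)) dp <- info_dp[i]
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      for (ai in unique(alleles[alleles > 0L])) {
        if (ai > length(alts)) next
        geno <- if (all(alleles == ai)) "hom_alt" else "het"
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, chrom = norm_chrom(fix[i, "CHROM"]),
          pos = as.integer(fix[i, "POS"]),
          ref = toupper(fix[i, "REF"]), alt = toupper(alts[ai]),
          qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
          depth = dp, genotype = geno, filter = filt[i],
          stringsAsFactors = FALSE)
      }
    }
    out[[si]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  if (n_missing_gt > 0L) {
    warning(n_missing_gt, " record(s) without a usable GT skipped in ", path,
            call. = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- variant_calls(character(), character(), integer(),
                         character(), character())[0, ]
  }
  rownames(res) <- NULL
  res
}

#' Write a variant-call table as VCF
#'
#' One VCF row per distinct (chrom, pos, ref, alt); per-sample GT:DP columns.
#' Filter flags are mirrored into the FILTER column (PASS when no sample's
#' record carries a flag, else the semicolon-joined union). Output is
#' gzip-compressed; use a `.vcf.gz` path.
#'
#' @param calls Variant-call `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  stopifnot(nrow(calls) > 0L)
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
  ukey <- unique(key[ord])
  idx1 <- match(ukey, key)
  samples <- sort(unique(calls$sample_id))
  filt <- vapply(ukey, function(k) {
    f <- unique(unlist(strsplit(calls$filter[key == k], ";", fixed = TRUE)))
    f <- f[nzchar(f)]
    if (length(f)) paste(sort(f), collapse = ";") else "PASS"
  }, "", USE.NAMES = FALSE)
  fix <- cbind(CHROM = calls$chrom[idx1],
               POS = as.character(calls$pos[idx1]),
               ID = ".",
               REF = calls$ref[idx1], ALT = calls$alt[idx1],
               QUAL = as.character(calls$qual[idx1]),
               FILTER = filt,
               INFO = ".")
  gt <- matrix("./.", nrow = length(ukey), ncol = length(samples) + 1L,
               dimnames = list(NULL, c("FORMAT", samples)))
  gt[, "FORMAT"] <- "GT:DP"
  ri <- match(key, ukey)
  ci <- match(calls$sample_id, samples) + 1L
  gtstr <- ifelse(calls$genotype == "hom_alt", "1/1", "0/1")
  gt[cbind(ri, ci)] <- paste0(gtstr, ":", calls$depth)
  flags <- setdiff(unique(unlist(strsplit(calls$filter, ";", fixed = TRUE))), "")
  meta <- c("##fileformat=VCFv4.2",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
            sprintf('##FILTER=<ID=%s,Description="%s">', flags, flags))
  obj <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Normalize variant alleles against the reference
#'
#' SNVs are reference-checked and left unchanged. Indels are normalized to
#' their parsimonious, left-aligned representation: shared trailing bases are
#' trimmed (extending to the left with reference bases when an allele would
#' empty), then shared leading bases are trimmed.
#'
#' @param calls Variant-call `data.frame`.
#' @param ref Reference (see [load_reference()]).
#' @return The call table with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(calls, ref) {
  if (!nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    r <- calls$ref[i]; a <- calls$alt[i]; p <- calls$pos[i]
    chrom <- calls$chrom[i]
    obs <- ref_bases(ref, chrom, p, p + nchar(r) - 1L)
    if (obs != r) {
      stop("reference mismatch at ", chrom, ":", p, " (expected ", r,
           ", reference has ", obs, ")", call. = FALSE)
    }
    if (nchar(r) == 1L && nchar(a) == 1L) next
    repeat {
      nr <- nchar(r); na <- nchar(a)
      if (nr > 0L && na > 0L &&
          substr(r, nr, nr) == substr(a, na, na)) {
        r <- substr(r, 1L, nr - 1L); a <- substr(a, 1L, na - 1L)
        if (nchar(r) == 0L || nchar(a) == 0L) {
          if (p == 1L) stop("cannot left-extend at chromosome start", call. = FALSE)
          p <- p - 1L
          b <- ref_bases(ref, chrom, p)
          r <- paste0(b, r); a <- paste0(b, a)
        }
        next
      }
      if (nr >= 2L && na >= 2L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
        r <- substr(r, 2L, nr); a <- substr(a, 2L, na); p <- p + 1L
        next
      }
      break
    }
    calls$ref[i] <- r; calls$alt[i] <- a; calls$pos[i] <- p
  }
  calls
}
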