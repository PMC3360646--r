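# The rare-variant reduction cascade with per-stage accounting:
#   S1 exonic (coding classes + UTR/exonic non-coding + splice sites)
#   S2 coding / splice-relevant (drops mid-exon synonymous and UTR)
#   S3 not present in the in-house exome database
#   S4 population allele frequency <= threshold (default 0.5%)
#   S5 in candidate-panel genes
# Filtering is presence/threshold-based on exact normalized alleles; counts
# are monotone non-increasing across stages by construction.

#' Population allele-frequency resource
#'
#' @param df `data.frame` with `chrom`, `pos`, `ref`, `alt`, `af` (allele
#'   frequency in `[0,1]`).
#' @param label Resource label (e.g. a release name).
#' @return An object of class `frequency_resource`. Variants absent from the
#'   resource look up as frequency 0.
#' @export
frequency_resource <- function(df, label = "population") {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "af") %in% names(df)))
  if (any(df$af < 0 | df$af > 1)) stop("allele frequencies outside [0,1]", call. = FALSE)
  af <- as.numeric(df$af)
  names(af) <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(names(af))) stop("duplicate variants in frequency resource", call. = FALSE)
  structure(list(af = af, label = label), class = "frequency_resource")
}

#' Look up allele frequencies
#'
#' @param resource A [frequency_resource()].
#' @param calls Variant-call table (or any table with chrom/pos/ref/alt).
#' @return Numeric vector of frequencies, 0 where absent.
#' @export
lookup_frequency <- function(resource, calls) {
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  af <- unname(resource$af[key])
  af[is.na(af)] <- 0
  af
}

#' In-house cohort database
#'
#' The allele set observed in a local exome cohort, used to strip platform
#' artifacts and locally common variants. Membership is exact-allele.
#'
#' @param keys Character vector of allele keys ([variant_key()]), or a table
#'   with chrom/pos/ref/alt columns.
#' @param n_samples Cohort size (individuals).
#' @param label Database label.
#' @return An object of class `cohort_db`.
#' @export
cohort_db <- function(keys, n_samples, label = "in-house") {
  if (is.data.frame(keys)) {
    keys <- variant_key(keys$chrom, keys$pos, keys$ref, keys$alt)
  }
  structure(list(keys = unique(as.character(keys)),
                 n_samples = as.integer(n_samples), label = label),
            class = "cohort_db")
}

#' @export
print.cohort_db <- function(x, ...) {
  cat(sprintf("<in-house database: %d alleles from %d samples (%s)>\n",
              length(x$keys), x$n_samples, x$label))
  invisible(x)
}

#' Build the in-house database from cohort VCFs
#'
#' @param paths Per-sample VCF paths.
#' @param ref Optional reference for allele normalization before insertion.
#' @param label Database label.
#' @return A [cohort_db()] holding the union of (normalized) alleles.
#' @export
build_inhouse_db <- function(paths, ref = NULL, label = "in-house") {
  stopifnot(length(paths) >= 1L)
  seen <- character()
  keys <- character()
  for (p in paths) {
    calls <- read_vcf(p)
    sid <- unique(calls$sample_id)
    dup <- intersect(sid, seen)
    if (length(dup)) {
      stop("duplicate sample identifier(s) in cohort: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    seen <- c(seen, sid)
    if (!is.null(ref)) calls <- normalize_variants(calls, ref)
    keys <- c(keys, variant_key(calls$chrom, calls$pos, calls$ref, calls$alt))
  }
  cohort_db(keys, n_samples = length(paths), label = label)
}

#' Pipeline configuration
#'
#' @param maf_threshold Population minor-allele-frequency cutoff as a
#'   fraction; variants with frequency strictly greater are excluded
#'   (default 0.005, i.e. 0.5%; a variant at exactly 0.5% is retained).
#' @param qc Site-filter thresholds ([qc_thresholds()]).
#' @param splice_window Splice-site half-width in bp (default 2).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_threshold = 0.005, qc = qc_thresholds(),
                            splice_window = 2L) {
  stopifnot(maf_threshold > 0, maf_threshold < 0.5)
  structure(list(maf_threshold = maf_threshold, qc = qc,
                 splice_window = as.integer(splice_window)),
            class = "pipeline_config")
}

stage_labels <- c("all_exonic", "exonic_coding", "not_in_inhouse",
                  "rare_population", "panel_candidates")

exonic_categories <- c("splice_site", "synonymous", "missense", "stop_gain",
                       "stop_loss", "frameshift_indel", "inframe_indel",
                       "noncoding_exonic")

#' Run the reduction cascade
#'
#' @param calls QC-passing variant-call `data.frame` (rows with non-empty
#'   filter flags are ignored).
#' @param annotations Annotation table ([annotate_variants()] output, or any
#'   table with chrom/pos/ref/alt, gene, category, at_exon_boundary); every
#'   call must be covered.
#' @param db In-house database ([cohort_db()]), or NULL for none.
#' @param freq Population frequencies ([frequency_resource()]), or NULL.
#' @param panel Gene panel ([gene_panel()]), or NULL to skip the panel stage.
#' @param config A [pipeline_config()].
#' @return A list:
#'   * `survivors`: calls surviving all stages, with annotation columns,
#'     `resource_freq`, and `in_inhouse_db` attached;
#'   * `report`: per-sample stage counts (`data.frame`, one row per sample,
#'     columns `all_exonic`, `exonic_coding`, `not_in_inhouse`,
#'     `rare_population`, `panel_candidates`);
#'   * `rare`: calls surviving through the frequency stage (input to
#'     [recurrence_summary()]).
#' @export
reduce_variants <- function(calls, annotations, db = NULL, freq = NULL,
                            panel = NULL, config = pipeline_config()) {
  calls <- passing(calls)
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  akey <- variant_key(annotations$chrom, annotations$pos,
                      annotations$ref, annotations$alt)
  m <- match(key, akey)
  if (anyNA(m)) {
    missing <- unique(key[is.na(m)])
    stop("unannotated variant(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L),
         call. = FALSE)
  }
  ann_cols <- setdiff(names(annotations), c("chrom", "pos", "ref", "alt"))
  calls <- cbind(calls, annotations[m, ann_cols, drop = FALSE])
  rownames(calls) <- NULL
  if (!"at_exon_boundary" %in% names(calls)) calls$at_exon_boundary <- FALSE

  s1 <- calls$category %in% exonic_categories
  s2 <- s1 & is_reduction_coding(calls$category, calls$at_exon_boundary)
  calls$in_inhouse_db <- if (is.null(db)) FALSE else key %in% db$keys
  s3 <- s2 & !calls$in_inhouse_db
  calls$resource_freq <- if (is.null(freq)) 0 else lookup_frequency(freq, calls)
  s4 <- s3 & calls$resource_freq <= config$maf_threshold
  s5 <- if (is.null(panel)) s4 else s4 & calls$gene %in% panel$entries$gene

  samples <- sort(unique(calls$sample_id))
  count_by <- function(keep) {
    as.integer(table(factor(calls$sample_id[keep], levels = samples)))
  }
  report <- data.frame(sample_id = samples,
                       all_exonic = count_by(s1),
                       exonic_coding = count_by(s2),
                       not_in_inhouse = count_by(s3),
                       rare_population = count_by(s4),
                       panel_candidates = count_by(s5),
                       stringsAsFactors = FALSE)
  list(survivors = calls[s5, , drop = FALSE],
       report = report,
       rare = calls[s4, , drop = FALSE])
}

#' Cross-sample recurrence of rare variants
#'
#' Summarizes sharing of post-frequency-filter variants across samples:
#' variants (exact alleles) seen in two or more samples, and genes hit by
#' rare variants (most often different ones) in two or more, and three or
#' more, samples.
#'
#' @param rare Post-frequency-stage calls (`rare` element of
#'   [reduce_variants()]), covering all samples.
#' @return List with `n_distinct_variants`, `n_distinct_genes`,
#'   `n_variants_shared`, `n_genes_ge2`, `n_genes_ge3`.
#' @export
recurrence_summary <- function(rare) {
  if (length(unique(rare$sample_id)) < 2L) {
    stop("recurrence summary needs at least two samples", call. = FALSE)
  }
  key <- variant_key(rare$chrom, rare$pos, rare$ref, rare$alt)
  vtab <- table(tapply(rare$sample_id, key, function(s) length(unique(s))))
  v_sharing <- tapply(rare$sample_id, key, function(s) length(unique(s)))
  g_sharing <- tapply(rare$sample_id, rare$gene, function(s) length(unique(s)))
  list(n_distinct_variants = length(v_sharing),
       n_distinct_genes = length(g_sharing),
       n_variants_shared = sum(v_sharing >= 2L),
       n_genes_ge2 = sum(g_sharing >= 2L),
       n_genes_ge3 = sum(g_sharing >= 3L))
}
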