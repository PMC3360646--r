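# Site-level SNP quality filters: minimum depth, minimum site quality, and
# the 10-bp SNP-cluster rule. Filtering only sets flags; no records are
# removed, and downstream stages consume the flag-free subset.

#' Site-filter thresholds
#'
#' Defaults follow common practice for exome SNP filtration: depth >= 8
#' reads, site quality >= 30 (phred), and no SNV in a cluster of >= 3 SNVs
#' within any 10-bp window. Boundary values pass.
#'
#' @param min_depth Minimum read depth (reads).
#' @param min_qual Minimum phred-scaled site quality.
#' @param cluster_window Cluster window size (bp).
#' @param cluster_count Number of SNVs within one window that defines a
#'   cluster.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_depth = 8, min_qual = 30,
                          cluster_window = 10, cluster_count = 3) {
  stopifnot(min_depth > 0, min_qual > 0, cluster_window > 0, cluster_count > 0)
  structure(list(min_depth = min_depth, min_qual = min_qual,
                 cluster_window = as.integer(cluster_window),
                 cluster_count = as.integer(cluster_count)),
            class = "qc_thresholds")
}

add_flag <- function(filter, flag, which) {
  out <- filter
  for (i in which(which)) {
    f <- unique(c(strsplit(out[i], ";", fixed = TRUE)[[1]], flag))
    f <- sort(f[nzchar(f)])
    out[i] <- paste(f, collapse = ";")
  }
  out
}

#' Apply depth and quality site filters
#'
#' Flags calls with depth below `min_depth` as `low_depth` and calls with
#' site quality below `min_qual` as `low_qual`. Boundary values (depth equal
#' to the threshold, quality equal to the threshold) pass. Idempotent.
#'
#' @param calls Variant-call `data.frame` with `depth` and `qual` populated.
#' @param thresholds A [qc_thresholds()] object.
#' @return The call table with `filter` flags updated.
#' @export
apply_site_filters <- function(calls, thresholds = qc_thresholds()) {
  if (!nrow(calls)) return(calls)
  calls$filter <- add_flag(calls$filter, "low_depth",
                           !is.na(calls$depth) & calls$depth < thresholds$min_depth)
  calls$filter <- add_flag(calls$filter, "low_qual",
                           !is.na(calls$qual) & calls$qual < thresholds$min_qual)
  calls
}

#' Flag SNV clusters
#'
#' An SNV is flagged `snp_cluster` when any window of `cluster_window`
#' consecutive bases contains at least `cluster_count` SNVs from the same
#' sample on the same chromosome. Indels are exempt from this rule. The
#' result does not depend on input row order.
#'
#' @param calls Variant-call `data.frame`.
#' @param thresholds A [qc_thresholds()] object.
#' @return The call table with `filter` flags updated.
#' @export
flag_snp_clusters <- function(calls, thresholds = qc_thresholds()) {
  if (!nrow(calls)) return(calls)
  is_snv <- nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
  w <- thresholds$cluster_window
  k <- thresholds$cluster_count
  grp <- paste(calls$sample_id, calls$chrom, sep = "\r")
  flagged <- logical(nrow(calls))
  for (g in unique(grp[is_snv])) {
    idx <- which(is_snv & grp == g)
    pos <- calls$pos[idx]
    # distinct positions (two alt alleles at one site count once)
    upos <- sort(unique(pos))
    n <- length(upos)
    if (n < k) next
    inclust <- logical(n)
    for (j in seq_len(n - k + 1L)) {
      if (upos[j + k - 1L] - upos[j] <= w - 1L) {
        inclust[j:(j + k - 1L)] <- TRUE
      }
    }
    flagged[idx[pos %in% upos[inclust]]] <- TRUE
  }
  calls$filter <- add_flag(calls$filter, "snp_cluster", flagged)
  calls
}

#' QC-passing subset
#'
#' @param calls Variant-call `data.frame`.
#' @return Rows whose filter-flag set is empty.
#' @export
passing <- function(calls) {
  calls[!nzchar(calls$filter), , drop = FALSE]
}
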