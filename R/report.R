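# Report assembly: write the per-module tables under one run directory with
# fixed file names, plus a JSON manifest recording parameters and seed.

#' Write a run report directory
#'
#' Writes whichever components are supplied under fixed names:
#' `reduction_report.tsv` (one row per sample, one column per cascade
#' stage), `candidates.tsv` (cascade survivors), `triage_report.tsv`,
#' `coverage_summary.tsv`, `per_gene_coverage.tsv`, `concordance.tsv` and
#' `manifest.json`.
#'
#' @param dir Output directory (created if needed).
#' @param reduction A [reduce_variants()] result.
#' @param triage A [triage_candidates()] table.
#' @param coverage A coverage-summary table ([coverage_summary()] rows).
#' @param gene_coverage A [per_gene_coverage()] table.
#' @param concordance A [het_concordance()] table.
#' @param manifest Named list of run parameters (seed, thresholds, ...).
#' @return Named list of written paths, invisibly.
#' @export
write_run_report <- function(dir, reduction = NULL, triage = NULL,
                             coverage = NULL, gene_coverage = NULL,
                             concordance = NULL, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(reduction)) {
    paths$reduction_report <- wt(reduction$report, "reduction_report.tsv")
    surv <- reduction$survivors
    surv <- surv[, !vapply(surv, is.list, TRUE), drop = FALSE]
    paths$candidates <- wt(surv, "candidates.tsv")
  }
  if (!is.null(triage)) {
    tri <- triage[, !vapply(triage, is.list, TRUE), drop = FALSE]
    paths$triage_report <- wt(tri, "triage_report.tsv")
  }
  if (!is.null(coverage)) paths$coverage_summary <- wt(coverage, "coverage_summary.tsv")
  if (!is.null(gene_coverage)) paths$per_gene_coverage <- wt(gene_coverage, "per_gene_coverage.tsv")
  if (!is.null(concordance)) paths$concordance <- wt(concordance, "concordance.tsv")
  manifest$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$manifest <- p
  invisible(paths)
}
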