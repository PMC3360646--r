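# Rule-based pathogenicity triage of panel candidates: in-silico predictor
# verdict aggregation, control-cohort frequency, Sanger validation status
# and family segregation, combined into a documented, configurable cascade.
#
# The predictors themselves (SIFT, PolyPhen-2, Align-GVGD) are never run
# here; their verdicts are inputs.

agvgd_levels <- c("C0", "C15", "C25", "C35", "C45", "C55", "C65")
pp2_levels <- c("benign", "possibly_damaging", "probably_damaging")

#' Aggregate in-silico predictor verdicts
#'
#' Damaging criteria (defaults): SIFT `not_tolerated`; PolyPhen-2 at least
#' `possibly_damaging`; Align-GVGD class at least `C35`. The overall call is
#' `damaging` when at least `min_votes` of the available verdicts are
#' damaging, `benign` when none is, `mixed` otherwise, and `uninformative`
#' when all three are unavailable. Unavailable verdicts leave the
#' denominator, so a single available damaging verdict is called damaging.
#'
#' @param sift `"tolerated"`, `"not_tolerated"` or `"unavailable"`.
#' @param polyphen2 `"benign"`, `"possibly_damaging"`,
#'   `"probably_damaging"` or `"unavailable"`.
#' @param agvgd `"C0"` ... `"C65"` or `"unavailable"`.
#' @param agvgd_min Minimum Align-GVGD class counted damaging.
#' @param pp2_min Minimum PolyPhen-2 class counted damaging.
#' @param min_votes Damaging votes needed for an overall `damaging` call
#'   when two or more verdicts are available (default 2).
#' @return List with `n_available`, `n_damaging`, `call`.
#' @export
aggregate_predictors <- function(sift, polyphen2, agvgd,
                                 agvgd_min = "C35",
                                 pp2_min = "possibly_damaging",
                                 min_votes = 2L) {
  sift <- match.arg(sift, c("tolerated", "not_tolerated", "unavailable"))
  polyphen2 <- match.arg(polyphen2, c(pp2_levels, "unavailable"))
  agvgd <- match.arg(agvgd, c(agvgd_levels, "unavailable"))
  votes <- c(
    if (sift != "unavailable") sift == "not_tolerated",
    if (polyphen2 != "unavailable")
      match(polyphen2, pp2_levels) >= match(pp2_min, pp2_levels),
    if (agvgd != "unavailable")
      match(agvgd, agvgd_levels) >= match(agvgd_min, agvgd_levels)
  )
  n_avail <- length(votes)
  n_dam <- sum(votes)
  call <- if (n_avail == 0L) "uninformative"
    else if (n_dam >= min(min_votes, n_avail) && n_dam > 0L) "damaging"
    else if (n_dam == 0L) "benign"
    else "mixed"
  list(n_available = n_avail, n_damaging = n_dam, call = call)
}

#' Assess family segregation of a candidate variant
#'
#' @param obs `data.frame` of tested relatives (beyond the proband) with
#'   columns `affected` (`affected`/`unaffected`/`IGT`) and `carrier`
#'   (`carrier`/`non-carrier`/`untested`). Zero rows = only the proband was
#'   available.
#' @return `"co-segregates"` when at least one tested affected relative
#'   carries the variant and nothing contradicts; `"does_not_cosegregate"`
#'   when a tested affected relative is a non-carrier or a tested unaffected
#'   adult relative carries it (impaired glucose tolerance counts as
#'   neither affected nor unaffected); otherwise `"uninformative"`.
#' @export
assess_segregation <- function(obs) {
  if (is.null(obs) || !nrow(obs)) return("uninformative")
  stopifnot(all(c("affected", "carrier") %in% names(obs)))
  tested <- obs[obs$carrier != "untested", , drop = FALSE]
  if (!nrow(tested)) return("uninformative")
  contradiction <-
    any(tested$affected == "affected" & tested$carrier == "non-carrier") ||
    any(tested$affected == "unaffected" & tested$carrier == "carrier")
  if (contradiction) return("does_not_cosegregate")
  if (any(tested$affected == "affected" & tested$carrier == "carrier")) {
    return("co-segregates")
  }
  "uninformative"
}

#' Classify one candidate variant
#'
#' Rule cascade (in order):
#' 1. validation failed -> `excluded_false_positive`;
#' 2. control-cohort allele frequency above `maf_threshold` ->
#'    `likely_benign`;
#' 3. gene with an established dominant-diabetes phenotype AND
#'    (truncating consequence, or overall damaging predictor call) AND
#'    control frequency at or below the threshold AND segregation not
#'    contradicted -> `pathogenic`;
#' 4. otherwise `uncertain`.
#'
#' @param gene_class `"known_dominant_diabetes"` or `"candidate"`.
#' @param category Consequence category.
#' @param control_freq Allele frequency in the healthy-control cohort
#'   (NA = not assayed; treated as passing rule 2 but failing nothing).
#' @param predictor_call Overall call from [aggregate_predictors()].
#' @param validation `"confirmed"`, `"failed"` or `"pending"`.
#' @param segregation Result of [assess_segregation()].
#' @param maf_threshold Control-frequency cutoff (default 0.005).
#' @return One of `"pathogenic"`, `"uncertain"`, `"likely_benign"`,
#'   `"excluded_false_positive"`.
#' @export
classify_candidate <- function(gene_class, category, control_freq,
                               predictor_call, validation, segregation,
                               maf_threshold = 0.005) {
  if (validation == "failed") return("excluded_false_positive")
  if (!is.na(control_freq) && control_freq > maf_threshold) return("likely_benign")
  truncating <- category %in% c("stop_gain", "frameshift_indel")
  if (gene_class == "known_dominant_diabetes" &&
      (truncating || predictor_call == "damaging") &&
      (is.na(control_freq) || control_freq <= maf_threshold) &&
      segregation != "does_not_cosegregate") {
    return("pathogenic")
  }
  "uncertain"
}

#' Triage a table of panel candidates
#'
#' Joins cascade survivors with their candidate metadata (predictor
#' verdicts, control frequencies, validation status, segregation
#' observations) and applies [classify_candidate()] to each.
#'
#' @param survivors Cascade survivors ([reduce_variants()] `survivors`).
#' @param meta Candidate metadata: `data.frame` keyed by `chrom`, `pos`,
#'   `ref`, `alt` with columns `sift`, `polyphen2`, `agvgd`,
#'   `control_freq`, `n_controls`, `validation`, and optionally
#'   `segregation` (a pre-assessed class) or a list-column
#'   `segregation_obs` of per-relative observations.
#' @param known_dominant Genes classed `known_dominant_diabetes`
#'   (default [known_dominant_diabetes_genes()]).
#' @param maf_threshold Control-frequency cutoff (default 0.005).
#' @return `data.frame`: one row per candidate with gene, variant names,
#'   frequencies, verdicts, predictor call, segregation, validation and
#'   `triage_class`.
#' @export
triage_candidates <- function(survivors, meta,
                              known_dominant = known_dominant_diabetes_genes(),
                              maf_threshold = 0.005) {
  key <- variant_key(survivors$chrom, survivors$pos, survivors$ref, survivors$alt)
  mkey <- variant_key(meta$chrom, meta$pos, meta$ref, meta$alt)
  m <- match(key, mkey)
  if (anyNA(m)) {
    stop("candidate metadata missing for: ",
         paste(utils::head(unique(key[is.na(m)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(survivors)
  out <- survivors[, intersect(c("sample_id", "chrom", "pos", "ref", "alt",
                                 "gene", "category", "c_name", "p_name",
                                 "resource_freq"), names(survivors))]
  out$sift <- meta$sift[m]
  out$polyphen2 <- meta$polyphen2[m]
  out$agvgd <- meta$agvgd[m]
  out$control_freq <- meta$control_freq[m]
  out$n_controls <- if ("n_controls" %in% names(meta)) meta$n_controls[m] else NA_integer_
  out$validation <- meta$validation[m]
  out$gene_class <- ifelse(out$gene %in% known_dominant,
                           "known_dominant_diabetes", "candidate")
  seg <- character(n); pcall <- character(n)
  for (i in seq_len(n)) {
    agg <- aggregate_predictors(out$sift[i], out$polyphen2[i], out$agvgd[i])
    pcall[i] <- agg$call
    seg[i] <- if ("segregation" %in% names(meta) && !is.na(meta$segregation[m[i]])) {
      meta$segregation[m[i]]
    } else if ("segregation_obs" %in% names(meta)) {
      assess_segregation(meta$segregation_obs[[m[i]]])
    } else "uninformative"
  }
  out$predictor_call <- pcall
  out$segregation <- seg
  out$triage_class <- vapply(seq_len(n), function(i) {
    classify_candidate(out$gene_class[i], out$category[i], out$control_freq[i],
                       pcall[i], out$validation[i], seg[i], maf_threshold)
  }, "")
  rownames(out) <- NULL
  out
}
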