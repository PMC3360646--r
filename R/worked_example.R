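# The printed worked example: the 14 rare candidate-panel variants found in
# the nine-proband diagnostic-exome cohort, encoded as a machine-readable
# fixture (calls, annotations, frequencies, predictor verdicts, validation
# status and family-segregation facts), plus seeded decoy variants that the
# reduction cascade must remove (common, in-house, mid-exon synonymous,
# non-coding and off-panel alleles).

worked_example_rows <- function() {
  # gene, chrom, pos, c_name, p_name, category, patient, resource_freq,
  # dbsnp, control_freq, sift, polyphen2, agvgd, validation, segregation
  rows <- rbind(
    c("ABCC8", "11", 17418486, "c.4096G>A", "p.A1366T", "missense", "P03",
      0, "", 0, "tolerated", "possibly_damaging", "C55", "confirmed", ""),
    c("ALMS1", "2", 73677199, "c.3542C>T", "p.T1181I", "missense", "P09",
      0, "", 0.001, "unavailable", "possibly_damaging", "unavailable",
      "confirmed", ""),
    c("ARAP1", "11", 72421497, "c.1349G>A", "p.R450H", "missense", "P04",
      0, "", 0, "not_tolerated", "benign", "C0", "confirmed", "cosegregates"),
    c("CRY2", "11", 45893711, "c.1528G>C", "p.G510R", "missense", "P02",
      0, "", 0.001, "tolerated", "benign", "C15", "confirmed", ""),
    c("GLIS3", "9", 4286332, "c.94C>G", "p.R32G", "missense", "P03",
      0, "", 0, "not_tolerated", "possibly_damaging", "C0", "confirmed", ""),
    c("HADH", "4", 108940732, "c.456G>T", "p.Q152H", "missense", "P09",
      0.002, "rs1051519", NA, "tolerated", "benign", "C0", "confirmed", ""),
    c("HNF4A", "20", 43034848, "c.266G>A", "p.R89Q", "missense", "P07",
      0, "", 0, "not_tolerated", "probably_damaging", "C35", "confirmed",
      "cosegregates"),
    c("MADD", "11", 47317569, "c.3479G>C", "p.S1160T", "missense", "P02",
      0, "", 0, "tolerated", "probably_damaging", "C55", "confirmed",
      "cosegregates"),
    c("NOTCH2", "1", 120468211, "c.4228C>T", "p.R1410C", "missense", "P05",
      0, "", 0, "not_tolerated", "possibly_damaging", "C25", "confirmed",
      "contradicts"),
    c("NOTCH2", "1", 120478125, "c.3625T>G", "p.F1209V", "missense", "P03",
      0, "", 0.004, "not_tolerated", "possibly_damaging", "C45", "confirmed", ""),
    c("NOTCH2", "1", 120548095, "c.272G>T", "p.R91L", "missense", "P05",
      0, "", NA, "unavailable", "unavailable", "unavailable", "failed", ""),
    c("PPARG", "3", 1258536, "c.1071G>A", "p.R357X", "stop_gain", "P01",
      0, "", 0, "unavailable", "unavailable", "unavailable", "confirmed", ""),
    c("SREBF1", "17", 17718592, "c.2435G>A", "p.R812Q", "missense", "P09",
      0, "", 0.010, "tolerated", "benign", "C0", "confirmed", ""),
    c("WFS1", "4", 6354530, "c.2107C>T", "p.R703C", "missense", "P09",
      0, "", 0, "not_tolerated", "probably_damaging", "C65", "confirmed",
      "contradicts")
  )
  df <- data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- c("gene", "chrom", "pos", "c_name", "p_name", "category",
                 "patient", "resource_freq", "dbsnp", "control_freq",
                 "sift", "polyphen2", "agvgd", "validation", "segregation_kind")
  df$pos <- as.integer(df$pos)
  df$resource_freq <- as.numeric(df$resource_freq)
  df$control_freq <- suppressWarnings(as.numeric(df$control_freq))
  # substitution alleles from the c. name (fixture genome convention:
  # coding strand = reference strand)
  df$ref <- sub("^c\\.\\d+([ACGT])>([ACGT])$", "\\1", df$c_name)
  df$alt <- sub("^c\\.\\d+([ACGT])>([ACGT])$", "\\2", df$c_name)
  df
}

# Per-relative segregation observations matching the published family facts
worked_example_segregation <- function(kind) {
  switch(kind,
    cosegregates = data.frame(affected = "affected", carrier = "carrier",
                              stringsAsFactors = FALSE),
    contradicts = data.frame(affected = c("affected", "affected"),
                             carrier = c("carrier", "non-carrier"),
                             stringsAsFactors = FALSE),
    data.frame(affected = character(), carrier = character(),
               stringsAsFactors = FALSE)
  )
}

#' Encode the printed worked example as pipeline inputs
#'
#' Builds the 14 published candidate-panel variants (with their patients,
#' population and control frequencies, predictor verdicts, validation
#' status and family-segregation observations) together with seeded decoy
#' variants the cascade must eliminate: population-common alleles, alleles
#' present in the in-house database, mid-exon synonymous changes, intronic
#' and UTR variants, and rare coding variants outside the candidate panel.
#'
#' @param n_decoys Total decoy variants (>= 50; default 70).
#' @param seed Integer seed for decoy placement.
#' @return List: `calls`, `annotations`, `db`, `freq`,
#'   `panel` ([default_panel()]), `meta` (candidate metadata for
#'   [triage_candidates()], with `segregation_obs` list-column),
#'   `candidate_rows` (the 14 encoded rows).
#' @export
worked_example <- function(n_decoys = 70L, seed = 101L) {
  stopifnot(n_decoys >= 50L)
  cand <- worked_example_rows()
  set.seed(seed)
  patients <- sprintf("P%02d", 1:9)
  panel_genes <- default_panel()$entries$gene

  n_common <- 20L
  n_syn <- 15L
  n_indb <- 10L
  n_offpanel <- 10L
  n_noncod <- n_decoys - n_common - n_syn - n_indb - n_offpanel  # intronic/UTR
  stopifnot(n_noncod >= 5L)
  mk <- function(n, genes, category, af, in_db = FALSE, boundary = FALSE) {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    data.frame(gene = sample(genes, n, replace = TRUE),
               chrom = "12", pos = sample(1e6:2e6, n),
               ref = ref, alt = alt, category = category,
               patient = sample(patients, n, replace = TRUE),
               af = af, in_db = in_db, at_exon_boundary = boundary,
               stringsAsFactors = FALSE)
  }
  decoys <- rbind(
    mk(n_common, c(panel_genes, "OFFP1", "OFFP2"), "missense",
       af = stats::runif(n_common, 0.01, 0.35)),
    mk(n_syn, panel_genes, "synonymous", af = 0),
    mk(n_indb, panel_genes, "missense", af = 0, in_db = TRUE),
    mk(n_offpanel, c("OFFP1", "OFFP2", "OFFP3"), "missense",
       af = stats::runif(n_offpanel, 0, 0.004)),
    mk(n_noncod, panel_genes,
       sample(c("intronic", "noncoding_exonic"), n_noncod, replace = TRUE),
       af = 0)
  )
  decoys <- decoys[!duplicated(paste(decoys$chrom, decoys$pos)), , drop = FALSE]

  calls <- variant_calls(
    sample_id = c(cand$patient, decoys$patient),
    chrom = c(cand$chrom, decoys$chrom), pos = c(cand$pos, decoys$pos),
    ref = c(cand$ref, decoys$ref), alt = c(cand$alt, decoys$alt),
    qual = 150, depth = 45, genotype = "het")
  annotations <- data.frame(
    chrom = norm_chrom(c(cand$chrom, decoys$chrom)),
    pos = c(cand$pos, decoys$pos),
    ref = c(cand$ref, decoys$ref), alt = c(cand$alt, decoys$alt),
    gene = c(cand$gene, decoys$gene),
    transcript_id = NA_character_,
    category = c(cand$category, decoys$category),
    c_name = c(cand$c_name, rep("", nrow(decoys))),
    p_name = c(cand$p_name, rep("", nrow(decoys))),
    at_exon_boundary = c(rep(FALSE, nrow(cand)), decoys$at_exon_boundary),
    stringsAsFactors = FALSE)

  freq_rows <- rbind(
    data.frame(chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$alt,
               af = cand$resource_freq, stringsAsFactors = FALSE),
    data.frame(chrom = decoys$chrom, pos = decoys$pos, ref = decoys$ref,
               alt = decoys$alt, af = decoys$af, stringsAsFactors = FALSE))
  freq <- frequency_resource(freq_rows[freq_rows$af > 0, , drop = FALSE],
                             label = "1000G-like interim frequencies")
  db <- cohort_db(decoys[decoys$in_db, c("chrom", "pos", "ref", "alt")],
                  n_samples = 50L, label = "in-house 50 exomes")

  meta <- cand[, c("chrom", "pos", "ref", "alt", "sift", "polyphen2", "agvgd",
                 "control_freq", "validation", "dbsnp")]
  meta$n_controls <- 340L
  meta$segregation_obs <- lapply(cand$segregation_kind, worked_example_segregation)
  list(calls = calls, annotations = annotations, db = db, freq = freq,
       panel = default_panel(), meta = meta, candidate_rows = cand)
}

#' Run the reduction cascade and triage on the worked example
#'
#' @param wex Output of [worked_example()] (built fresh by default).
#' @return List: `reduction` (the [reduce_variants()] result) and `triage`
#'   (the [triage_candidates()] table).
#' @export
run_worked_example <- function(wex = worked_example()) {
  red <- reduce_variants(wex$calls, wex$annotations, db = wex$db,
                         freq = wex$freq, panel = wex$panel)
  tri <- triage_candidates(red$survivors, wex$meta)
  list(reduction = red, triage = tri)
}
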