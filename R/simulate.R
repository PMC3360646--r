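# Seeded synthetic-data generator: toy reference genome with coding gene
# models, capture targets, candidate panel, per-sample exome variant sets
# calibrated to published diagnostic-exome magnitudes, in-house database,
# population frequency resource, spike-in pathogenic variants, array
# genotypes and per-base depth tracks.
#
# Calibration design: per-sample variant counts are Poisson around class
# expectations reverse-engineered from the printed stage averages
# (all-exonic 14,463; coding 6,633; not-in-in-house 253; rare 199; panel
# candidates ~2), so every stage expectation is analytically checkable.

#' Simulation parameters
#'
#' Defaults are the magnitudes of the diagnostic-exome study the package
#' models: nine probands, a 50-exome in-house database, 340 controls, 7,800
#' array SNPs per sample at 91% detection, 45X target median depth, and
#' per-sample expected stage counts 14,463 / 6,633 / 253 / 199 / 2.
#'
#' @param n_samples Number of probands.
#' @param n_inhouse In-house database cohort size.
#' @param n_controls Control-cohort size (individuals).
#' @param n_array_snps Array het sites per sample.
#' @param n_array_samples Samples with array data.
#' @param detection_prob Per-site sequencing detection probability.
#' @param median_depth Target median depth (X) of depth tracks.
#' @param exonic_per_sample,coding_per_sample,post_inhouse_per_sample,rare_per_sample,panel_per_sample
#'   Expected per-sample survivor counts at the five cascade stages.
#' @param scale Linear scale factor applied to the count expectations
#'   (e.g. 0.1 runs a 1/10-size cohort with proportionally scaled
#'   expectations).
#' @param n_genes Genes in the toy genome.
#' @param n_chroms Chromosomes in the toy genome.
#' @param het_fraction Fraction of heterozygous genotypes.
#' @param low_freq_share Share of rare variants drawn from a shared
#'   low-frequency pool (drives cross-sample recurrence); the rest are
#'   private novel alleles.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_samples = 9, n_inhouse = 50, n_controls = 340,
                       n_array_snps = 7800, n_array_samples = 7,
                       detection_prob = 0.91, median_depth = 45,
                       exonic_per_sample = 14463, coding_per_sample = 6633,
                       post_inhouse_per_sample = 253, rare_per_sample = 199,
                       panel_per_sample = 2, scale = 1,
                       n_genes = 300, n_chroms = 3,
                       het_fraction = 0.8, low_freq_share = 0.25) {
  stopifnot(detection_prob >= 0, detection_prob <= 1,
            het_fraction >= 0, het_fraction <= 1,
            low_freq_share >= 0, low_freq_share <= 1, scale > 0)
  if (!(exonic_per_sample > coding_per_sample &&
        coding_per_sample > post_inhouse_per_sample &&
        post_inhouse_per_sample > rare_per_sample &&
        rare_per_sample > panel_per_sample)) {
    stop("infeasible stage expectations: must be exonic > coding > ",
         "post-in-house > rare > panel", call. = FALSE)
  }
  p <- list(n_samples = as.integer(n_samples), n_inhouse = as.integer(n_inhouse),
            n_controls = as.integer(n_controls),
            n_array_snps = as.integer(n_array_snps),
            n_array_samples = as.integer(n_array_samples),
            detection_prob = detection_prob, median_depth = median_depth,
            exonic_per_sample = exonic_per_sample,
            coding_per_sample = coding_per_sample,
            post_inhouse_per_sample = post_inhouse_per_sample,
            rare_per_sample = rare_per_sample,
            panel_per_sample = panel_per_sample,
            scale = scale, n_genes = as.integer(n_genes),
            n_chroms = as.integer(n_chroms),
            het_fraction = het_fraction, low_freq_share = low_freq_share)
  # class expectations, after scaling
  p$e_noncoding <- (exonic_per_sample - coding_per_sample) * scale
  p$e_coding_in_db <- (coding_per_sample - post_inhouse_per_sample) * scale
  p$e_common_not_db <- (post_inhouse_per_sample - rare_per_sample) * scale
  p$e_private_rare <- (rare_per_sample - panel_per_sample) * scale
  p$e_panel_rare <- panel_per_sample * scale
  structure(p, class = "sim_params")
}

stop_free_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                            c("TAA", "TAG", "TGA"))

#' Generate the toy reference genome, gene models, capture targets and panel
#'
#' Builds `n_genes` protein-coding genes (multi-exon, both strands, CDS a
#' multiple of 3 translating without internal stops) laid out over
#' `n_chroms` chromosomes, with UTR bases on the terminal exons. The first
#' genes carry the default candidate-panel symbols; the capture targets are
#' the merged exon intervals of all genes except two panel genes (DGKB and
#' THADA), deliberately left off the capture design.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed (full determinism under a fixed seed).
#' @return List of class `sim_assets`: `ref` (DNAStringSet), `models`
#'   (`exomody_models`), `targets` (`GRanges`), `panel` ([gene_panel()]),
#'   `absent_genes`, `params`.
#' @export
generate_reference_and_genes <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- default_panel()
  panel_genes <- panel$entries$gene
  n_genes <- max(params$n_genes, length(panel_genes) + 5L)
  gene_names <- c(panel_genes,
                  sprintf("GENE%03d", seq_len(n_genes - length(panel_genes))))
  chrom_of <- rep(seq_len(params$n_chroms), length.out = n_genes)
  # shuffle so panel genes spread over chromosomes
  ord <- sample.int(n_genes)
  gene_names <- gene_names[ord]

  cursors <- rep(1000L, params$n_chroms)
  chrom_parts <- vector("list", params$n_chroms)
  txs <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    ch <- chrom_of[i]
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(2:6, 1L)
    cds_ex_len <- sample(seq(120L, 360L, by = 3L), n_ex, replace = TRUE)
    extra <- sum(cds_ex_len) %% 3L
    cds_ex_len[n_ex] <- cds_ex_len[n_ex] - extra
    introns <- sample(150:600, n_ex - 1L, replace = TRUE)
    utr_left <- 60L; utr_right <- 90L
    start <- cursors[ch] + sample(500:1500, 1L)
    # genomic exon layout (0-based half-open); UTR on terminal exons
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    cur <- start
    for (j in seq_len(n_ex)) {
      u5 <- if (j == 1L) utr_left else 0L
      u3 <- if (j == n_ex) utr_right else 0L
      ex_start[j] <- cur
      ex_end[j] <- cur + u5 + cds_ex_len[j] + u3
      cur <- ex_end[j] + if (j < n_ex) introns[j] else 0L
    }
    cds_start <- ex_start[1L] + utr_left
    cds_end <- ex_end[n_ex] - utr_right
    txs[[i]] <- new_transcript(paste0(gene_names[i], "-T1"), gene_names[i],
                               as.character(ch), strand,
                               ex_start, ex_end, cds_start, cds_end)
    cursors[ch] <- cur
  }
  chrom_len <- cursors + 1000L
  seqs <- vapply(chrom_len, random_dna, "")
  # implant stop-free CDS sequences
  for (tx in txs) {
    n_cod <- tx$cds_len %/% 3L
    cds_seq <- paste0("ATG",
                      paste(sample(stop_free_codons, n_cod - 2L, replace = TRUE),
                            collapse = ""),
                      "TAA")
    ch <- as.integer(tx$chrom)
    w <- tx$cds_exon_ends - tx$cds_exon_starts
    # slices of the coding sequence per cds exon, transcription order
    ord_ex <- if (tx$strand == "+") seq_along(w) else rev(seq_along(w))
    offs <- cumsum(c(0L, w[ord_ex]))
    for (k in seq_along(ord_ex)) {
      j <- ord_ex[k]
      chunk <- substr(cds_seq, offs[k] + 1L, offs[k + 1L])
      if (tx$strand == "-") chunk <- dna_revcomp(chunk)
      substr(seqs[ch], tx$cds_exon_starts[j] + 1L, tx$cds_exon_ends[j]) <- chunk
    }
  }
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- as.character(seq_len(params$n_chroms))
  models <- gene_models(txs)

  absent_genes <- intersect(c("DGKB", "THADA"), gene_names)
  target_txs <- models$transcripts[
    !vapply(models$transcripts, `[[`, "", "gene") %in% absent_genes]
  targets <- GenomicRanges::reduce(suppressWarnings(do.call(c, unname(lapply(target_txs, function(t) {
    GenomicRanges::GRanges(t$chrom,
                           IRanges::IRanges(t$exon_starts + 1L, t$exon_ends))
  })))), ignore.strand = TRUE)

  structure(list(ref = ref, models = models, targets = targets,
                 panel = panel, absent_genes = absent_genes, params = params),
            class = "sim_assets")
}

# Per-base position universes of the toy genome
asset_universes <- function(assets) {
  if (!is.null(assets$universes)) return(assets$universes)
  txs <- assets$models$transcripts
  cds <- do.call(rbind, lapply(txs, function(t) {
    data.frame(chrom = t$chrom,
               pos = unlist(mapply(function(s, e) seq.int(s + 1L, e),
                                   t$cds_exon_starts, t$cds_exon_ends,
                                   SIMPLIFY = FALSE)),
               gene = t$gene, stringsAsFactors = FALSE)
  }))
  utr <- do.call(rbind, lapply(txs, function(t) {
    allex <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                           t$exon_starts, t$exon_ends, SIMPLIFY = FALSE))
    cdspos <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                            t$cds_exon_starts, t$cds_exon_ends,
                            SIMPLIFY = FALSE))
    u <- setdiff(allex, cdspos)
    if (!length(u)) return(NULL)
    data.frame(chrom = t$chrom, pos = u, gene = t$gene, stringsAsFactors = FALSE)
  }))
  list(cds = cds, utr = utr)
}

# Vectorized single-base reference lookup
ref_base_vec <- function(ref, chrom, pos) {
  out <- character(length(pos))
  chrom <- norm_chrom(chrom)
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- as.character(Biostrings::extractAt(
      ref[[ch]], IRanges::IRanges(pos[i], pos[i])))
  }
  out
}

# Vectorized random non-reference base
random_alt_vec <- function(refb) {
  others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  others[cbind(match(refb, rownames(others)),
               sample.int(3L, length(refb), replace = TRUE))]
}

# Draw a pool of distinct variant sites from a position universe
draw_pool <- function(universe, n, ref, category_probs, maf_fun, in_db) {
  n <- min(n, nrow(universe))
  idx <- sample.int(nrow(universe), n)
  u <- universe[idx, , drop = FALSE]
  refb <- ref_base_vec(ref, u$chrom, u$pos)
  altb <- random_alt_vec(refb)
  cat <- sample(names(category_probs), n, replace = TRUE, prob = category_probs)
  data.frame(chrom = u$chrom, pos = u$pos, ref = refb, alt = altb,
             gene = u$gene, category = cat,
             at_exon_boundary = cat == "synonymous_boundary",
             af = maf_fun(n), in_db = in_db, stringsAsFactors = FALSE)
}

#' Generate a calibrated synthetic exome cohort
#'
#' Draws per-sample variant sets from shared pools so that the expected
#' per-stage survivor counts of the reduction cascade equal the configured
#' expectations: a common coding pool present in the in-house database, a
#' smaller common pool absent from it (removed only by the population
#' frequency filter), non-coding/mid-exon-synonymous variants (removed by
#' the coding filter), shared low-frequency and private novel rare variants,
#' and rare variants in panel genes. Per-sample class counts are Poisson.
#'
#' @param params A [sim_params()].
#' @param assets Genome assets ([generate_reference_and_genes()]).
#' @param seed Optional integer seed.
#' @return List of class `sim_cohort`: `calls`, `annotations`, `db`
#'   ([cohort_db()]), `freq` ([frequency_resource()]), `samples`,
#'   `expect` (analytic per-sample stage expectations), `params`.
#' @export
generate_cohort <- function(params = sim_params(), assets, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  uni <- asset_universes(assets)
  panel_genes <- assets$panel$entries$gene
  captured_panel <- setdiff(panel_genes, assets$absent_genes)
  cds_offpanel <- uni$cds[!uni$cds$gene %in% panel_genes, , drop = FALSE]
  cds_panel <- uni$cds[uni$cds$gene %in% captured_panel, , drop = FALSE]

  coding_cats <- c(missense = 0.90, stop_gain = 0.02, synonymous_boundary = 0.08)
  # shared pools
  pool_common <- draw_pool(uni$cds, ceiling(params$e_coding_in_db * 1.4),
                           assets$ref, coding_cats,
                           function(n) 0.005 + stats::rbeta(n, 0.3, 1.0) * 0.495,
                           in_db = TRUE)
  pool_noncod_utr <- draw_pool(uni$utr, ceiling((params$e_noncoding / 2) * 1.4),
                               assets$ref, c(noncoding_exonic = 1),
                               function(n) 0.005 + stats::rbeta(n, 0.3, 1.0) * 0.495,
                               in_db = TRUE)
  pool_noncod_syn <- draw_pool(uni$cds, ceiling((params$e_noncoding / 2) * 1.4),
                               assets$ref, c(synonymous = 1),
                               function(n) 0.005 + stats::rbeta(n, 0.3, 1.0) * 0.495,
                               in_db = TRUE)
  pool_common_nodb <- draw_pool(uni$cds, max(30L, ceiling(params$e_common_not_db * 2.5)),
                                assets$ref, c(missense = 1),
                                function(n) stats::runif(n, 0.0055, 0.05),
                                in_db = FALSE)
  e_lowfreq <- params$e_private_rare * params$low_freq_share
  pool_lowfreq <- draw_pool(cds_offpanel, max(20L, ceiling(e_lowfreq * 3)),
                            assets$ref, c(missense = 1),
                            function(n) stats::runif(n, 0.0001, 0.005),
                            in_db = FALSE)
  # drop pool collisions (same site drawn into two pools)
  pools <- list(common = pool_common, utr = pool_noncod_utr,
                syn = pool_noncod_syn, common_nodb = pool_common_nodb,
                lowfreq = pool_lowfreq)
  dup <- duplicated(unlist(lapply(pools, function(p) paste(p$chrom, p$pos))))
  off <- 0L
  for (nm in names(pools)) {
    n <- nrow(pools[[nm]])
    pools[[nm]] <- pools[[nm]][!dup[off + seq_len(n)], , drop = FALSE]
    off <- off + n
  }
  pool_sites <- unlist(lapply(pools, function(p) paste(p$chrom, p$pos)))

  draw_from <- function(pool, n) pool[sample.int(nrow(pool), min(n, nrow(pool))), , drop = FALSE]
  novel_rare <- function(universe, n, cats) {
    if (n == 0L) return(NULL)
    # oversample, drop collisions with shared pool sites, keep exactly n
    m <- min(ceiling(n * 1.3) + 20L, nrow(universe))
    p <- draw_pool(universe, m, assets$ref, cats, function(k) rep(0, k),
                   in_db = FALSE)
    p <- p[!paste(p$chrom, p$pos) %in% pool_sites, , drop = FALSE]
    p[seq_len(min(n, nrow(p))), , drop = FALSE]
  }

  samples <- sprintf("S%02d", seq_len(params$n_samples))
  per_sample <- lapply(samples, function(s) {
    parts <- list(
      draw_from(pools$common, stats::rpois(1L, params$e_coding_in_db)),
      draw_from(pools$utr, stats::rpois(1L, params$e_noncoding / 2)),
      draw_from(pools$syn, stats::rpois(1L, params$e_noncoding / 2)),
      draw_from(pools$common_nodb, stats::rpois(1L, params$e_common_not_db)),
      draw_from(pools$lowfreq, stats::rpois(1L, e_lowfreq)),
      novel_rare(cds_offpanel,
                 stats::rpois(1L, params$e_private_rare * (1 - params$low_freq_share)),
                 c(missense = 0.9, stop_gain = 0.05, synonymous_boundary = 0.05)),
      novel_rare(cds_panel, stats::rpois(1L, params$e_panel_rare),
                 c(missense = 0.8, stop_gain = 0.2))
    )
    v <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
    v <- v[!duplicated(paste(v$chrom, v$pos)), , drop = FALSE]
    v$sample_id <- s
    v
  })
  vars <- do.call(rbind, per_sample)
  n <- nrow(vars)
  calls <- variant_calls(
    sample_id = vars$sample_id, chrom = vars$chrom, pos = vars$pos,
    ref = vars$ref, alt = vars$alt,
    qual = round(30 + stats::rexp(n, 1 / 120)),
    depth = 8L + stats::rnbinom(n, mu = 40, size = 6),
    genotype = ifelse(stats::runif(n) < params$het_fraction, "het", "hom_alt")
  )
  ann_cat <- sub("synonymous_boundary", "synonymous", vars$category)
  annotations <- data.frame(
    chrom = norm_chrom(vars$chrom), pos = vars$pos, ref = vars$ref, alt = vars$alt,
    gene = vars$gene, transcript_id = NA_character_, category = ann_cat,
    c_name = "", p_name = "", at_exon_boundary = vars$at_exon_boundary,
    stringsAsFactors = FALSE)
  annotations <- annotations[!duplicated(
    variant_key(annotations$chrom, annotations$pos, annotations$ref, annotations$alt)), ]

  db_tab <- do.call(rbind, pools[c("common", "utr", "syn")])
  db <- cohort_db(db_tab, n_samples = params$n_inhouse,
                  label = sprintf("synthetic %d-exome cohort", params$n_inhouse))
  freq_tab <- do.call(rbind, pools)
  freq <- frequency_resource(
    freq_tab[freq_tab$af > 0, c("chrom", "pos", "ref", "alt", "af")],
    label = "synthetic population resource")

  expect <- list(
    all_exonic = params$e_noncoding + params$e_coding_in_db +
      params$e_common_not_db + params$e_private_rare + params$e_panel_rare,
    exonic_coding = params$e_coding_in_db + params$e_common_not_db +
      params$e_private_rare + params$e_panel_rare,
    not_in_inhouse = params$e_common_not_db + params$e_private_rare +
      params$e_panel_rare,
    rare_population = params$e_private_rare + params$e_panel_rare,
    panel_candidates = params$e_panel_rare)

  structure(list(calls = calls, annotations = annotations, db = db,
                 freq = freq, samples = samples, expect = expect,
                 params = params),
            class = "sim_cohort")
}

# Find a single-base substitution in a transcript with the requested
# consequence; returns list(pos, ref, alt) on the genomic strand, or NULL.
find_coding_snv <- function(tx, ref, want = c("stop_gain", "missense"),
                            max_tries = 200L) {
  want <- match.arg(want)
  seq <- cds_sequence(tx, ref)
  n_cod <- tx$cds_len %/% 3L
  for (try in seq_len(max_tries)) {
    ci <- sample.int(n_cod - 2L, 1L) + 1L  # skip start codon and stop codon
    codon <- substr(seq, 3L * ci - 2L, 3L * ci)
    aa0 <- translate_codon(codon)
    if (aa0 == "*") next
    for (off in sample.int(3L)) {
      b0 <- substr(codon, off, off)
      for (b1 in sample(setdiff(c("A", "C", "G", "T"), b0))) {
        alt_codon <- codon
        substr(alt_codon, off, off) <- b1
        aa1 <- translate_codon(alt_codon)
        hit <- if (want == "stop_gain") aa1 == "*" else (aa1 != aa0 && aa1 != "*")
        if (hit) {
          cpos <- 3L * (ci - 1L) + off
          gpos <- genomic_coordinate(tx, cpos)
          gref <- if (tx$strand == "+") b0 else comp_base(b0)
          galt <- if (tx$strand == "+") b1 else comp_base(b1)
          return(list(pos = gpos, ref = gref, alt = galt))
        }
      }
    }
  }
  NULL
}

#' Spike known-truth pathogenic variants into a cohort
#'
#' Injects `k` novel heterozygous variants (alternating stop-gain and
#' missense) into captured panel genes, absent from the in-house database
#' and the frequency resource, with passing depth and quality, and a
#' dominant-segregation family observation (an affected sibling carrying
#' the allele). Consequences are computed against the real gene models and
#' reference, so the spiked annotation is exactly what the annotator
#' produces.
#'
#' @param cohort A `sim_cohort` ([generate_cohort()]).
#' @param assets The matching `sim_assets`.
#' @param k Number of spike-ins.
#' @param seed Optional integer seed.
#' @return The cohort with spiked `calls`/`annotations`, plus `truth`: one
#'   row per spike (`sample_id`, variant, `gene`, `category`) with a
#'   list-column `segregation_obs`.
#' @export
spike_pathogenic <- function(cohort, assets, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (k == 0L) { cohort$truth <- NULL; return(cohort) }
  captured <- setdiff(assets$panel$entries$gene, assets$absent_genes)
  captured <- intersect(captured, names(assets$models$by_gene))
  if (!length(captured)) stop("no eligible panel gene for spike-in", call. = FALSE)
  used <- variant_key(cohort$calls$chrom, cohort$calls$pos,
                      cohort$calls$ref, cohort$calls$alt)
  truth <- list()
  new_calls <- list(); new_ann <- list()
  for (i in seq_len(k)) {
    want <- if (i %% 2L == 1L) "stop_gain" else "missense"
    repeat {
      g <- sample(captured, 1L)
      tx <- assets$models$transcripts[[assets$models$by_gene[[g]][1L]]]
      snv <- find_coding_snv(tx, assets$ref, want)
      if (is.null(snv)) next
      key <- variant_key(tx$chrom, snv$pos, snv$ref, snv$alt)
      if (key %in% used || key %in% names(cohort$freq$af) ||
          key %in% cohort$db$keys) next
      break
    }
    used <- c(used, key)
    s <- cohort$samples[(i - 1L) %% length(cohort$samples) + 1L]
    ann <- classify_variant(tx$chrom, snv$pos, snv$ref, snv$alt,
                            assets$models, assets$ref)
    stopifnot(ann$category == want)
    new_calls[[i]] <- variant_calls(s, tx$chrom, snv$pos, snv$ref, snv$alt,
                                    qual = 250, depth = 60, genotype = "het")
    new_ann[[i]] <- cbind(data.frame(chrom = tx$chrom, pos = snv$pos,
                                     ref = snv$ref, alt = snv$alt,
                                     stringsAsFactors = FALSE), ann)
    truth[[i]] <- data.frame(sample_id = s, chrom = tx$chrom, pos = snv$pos,
                             ref = snv$ref, alt = snv$alt, gene = g,
                             category = want, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth$segregation_obs <- replicate(nrow(truth), data.frame(
    affected = "affected", carrier = "carrier", stringsAsFactors = FALSE),
    simplify = FALSE)
  ann_new <- do.call(rbind, new_ann)
  ann_cols <- names(cohort$annotations)
  for (col in setdiff(ann_cols, names(ann_new))) ann_new[[col]] <- NA
  cohort$calls <- rbind(cohort$calls, do.call(rbind, new_calls))
  cohort$annotations <- rbind(cohort$annotations, ann_new[, ann_cols])
  cohort$truth <- truth
  cohort
}

#' Generate array genotypes consistent with a detection probability
#'
#' Samples `n_array_snps` heterozygous array sites per sample inside the
#' capture targets; each site is independently detected (present as a
#' matching het call in the sequencing calls) with probability
#' `detection_prob`, so the expected heterozygous-site concordance equals
#' `detection_prob` by construction.
#'
#' @param params A [sim_params()].
#' @param assets Genome assets.
#' @param seed Optional integer seed.
#' @param calls Optional existing call table to extend with the detected
#'   sites.
#' @return List: `array` (TSV-layout `data.frame`), `calls` (input calls
#'   plus detected het calls).
#' @export
generate_array_genotypes <- function(params = sim_params(), assets,
                                     seed = NULL, calls = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- region_bases(assets$targets)
  n_take <- min(params$n_array_snps, nrow(bases))
  samples <- sprintf("S%02d", seq_len(params$n_array_samples))
  arr <- list(); det_calls <- list()
  for (s in samples) {
    idx <- sample.int(nrow(bases), n_take)
    b <- bases[idx, , drop = FALSE]
    refb <- ref_base_vec(assets$ref, b$chrom, b$pos)
    altb <- random_alt_vec(refb)
    detected <- stats::runif(n_take) < params$detection_prob
    arr[[s]] <- data.frame(sample = s, chrom = b$chrom, pos = b$pos,
                           allele_A = refb, allele_B = altb, call = "AB",
                           stringsAsFactors = FALSE)
    if (any(detected)) {
      det_calls[[s]] <- variant_calls(s, b$chrom[detected], b$pos[detected],
                                      refb[detected], altb[detected],
                                      qual = 100, depth = 40, genotype = "het")
    }
  }
  list(array = do.call(rbind, c(arr, list(make.row.names = FALSE))),
       calls = do.call(rbind, c(list(calls), det_calls)))
}

#' Generate per-sample depth tracks over the capture targets
#'
#' Per-base depths are drawn from a right-skewed gamma distribution scaled
#' so its theoretical median equals the target median depth. Optionally, one
#' gene's CDS is forced to low coverage (emulating a poorly captured key
#' gene).
#'
#' @param params A [sim_params()].
#' @param assets Genome assets.
#' @param seed Optional integer seed.
#' @param samples Sample names (default the cohort's).
#' @param shape Gamma shape (default 4; smaller = more skewed).
#' @param low_coverage_gene Optional gene symbol whose CDS bases get
#'   near-zero depth.
#' @return Named list of depth tracks (`data.frame` with `chrom`, `pos`,
#'   `depth`), one per sample.
#' @export
generate_depth_tracks <- function(params = sim_params(), assets, seed = NULL,
                                  samples = sprintf("S%02d", seq_len(params$n_samples)),
                                  shape = 4, low_coverage_gene = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- region_bases(assets$targets)
  n <- nrow(bases)
  scale_f <- params$median_depth / stats::qgamma(0.5, shape)
  low_key <- character()
  if (!is.null(low_coverage_gene)) {
    lb <- region_bases(cds_granges(assets$models, low_coverage_gene))
    low_key <- paste(lb$chrom, lb$pos)
  }
  out <- lapply(samples, function(s) {
    d <- as.integer(round(stats::rgamma(n, shape) * scale_f))
    tr <- data.frame(chrom = bases$chrom, pos = bases$pos, depth = d,
                     stringsAsFactors = FALSE)
    if (length(low_key)) {
      hit <- paste(tr$chrom, tr$pos) %in% low_key
      tr$depth[hit] <- stats::rpois(sum(hit), 1.5)
    }
    tr
  })
  names(out) <- samples
  out
}
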