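# Shared fixtures, built in code. Heavier simulated assets are memoized so
# several test files can reuse one build.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small simulated genome shared across test files
small_assets <- function() {
  memo("small_assets", function() {
    generate_reference_and_genes(sim_params(scale = 0.1, n_genes = 40), seed = 2024)
  })
}

small_cohort <- function() {
  memo("small_cohort", function() {
    generate_cohort(sim_params(scale = 0.1, n_genes = 40), small_assets(), seed = 11)
  })
}

# Deterministic hand-built toy gene: 3 exons, CDS length 162 (54 codons),
# with a known implanted coding sequence; available on both strands as
# mirrored transcripts (identical CDS read on the coding strand).
#
# Layout (1-based): exon1 101-160 (UTR 101-120), exon2 201-280,
# exon3 341-400 (UTR 383-400); CDS 121..382.
toy_gene <- function() {
  memo("toy_gene", function() {
    set.seed(77)
    n_cod <- 54L
    cds_seq <- paste0(
      "ATG",
      paste(sample(setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA")),
                   n_cod - 2L, replace = TRUE), collapse = ""),
      "TAA")
    tx_p <- new_transcript("TOYP-T1", "TOYP", "1", "+",
                           c(100L, 200L, 340L), c(160L, 280L, 400L), 120L, 382L)
    tx_m <- new_transcript("TOYM-T1", "TOYM", "2", "-",
                           c(100L, 200L, 340L), c(160L, 280L, 400L), 120L, 382L)
    implant <- function(chrom_seq, tx, cds_seq) {
      w <- tx$cds_exon_ends - tx$cds_exon_starts
      ord <- if (tx$strand == "+") seq_along(w) else rev(seq_along(w))
      offs <- cumsum(c(0L, w[ord]))
      for (k in seq_along(ord)) {
        j <- ord[k]
        chunk <- substr(cds_seq, offs[k] + 1L, offs[k + 1L])
        if (tx$strand == "-") chunk <- dna_revcomp(chunk)
        substr(chrom_seq, tx$cds_exon_starts[j] + 1L, tx$cds_exon_ends[j]) <- chunk
      }
      chrom_seq
    }
    c1 <- implant(random_dna_str(600L), tx_p, cds_seq)
    c2 <- implant(random_dna_str(600L), tx_m, cds_seq)
    ref <- Biostrings::DNAStringSet(c("1" = c1, "2" = c2))
    list(cds_seq = cds_seq, tx_p = tx_p, tx_m = tx_m, ref = ref,
         models = gene_models(list(tx_p, tx_m)))
  })
}

translate_codon_str <- function(codon) Biostrings::GENETIC_CODE[[codon]]

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- independent oracles -------------------------------------------------

# Apply a variant to a chromosome string; used to check normalization
# preserves the edited haplotype.
apply_variant_to_seq <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# Brute-force SNP-cluster oracle: an SNV is clustered iff some w-bp window
# holds >= k distinct SNV positions of the same sample/chromosome.
cluster_oracle <- function(pos_all, pos_query, w = 10L, k = 3L) {
  upos <- sort(unique(pos_all))
  vapply(pos_query, function(p) {
    any(vapply(seq_along(upos), function(j) {
      lo <- upos[j]
      n_in <- sum(upos >= lo & upos <= lo + w - 1L)
      n_in >= k && p >= lo && p <= lo + w - 1L &&
        # p must be one of the k SNVs inside that window
        p %in% upos
    }, TRUE))
  }, TRUE)
}

# Brute-force reduction oracle: independent predicate evaluation per call.
reduce_oracle <- function(calls, annotations, db, freq, panel,
                          maf_threshold = 0.005) {
  calls <- calls[!nzchar(calls$filter), , drop = FALSE]
  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  akey <- variant_key(annotations$chrom, annotations$pos,
                      annotations$ref, annotations$alt)
  m <- match(key, akey)
  cat_ <- annotations$category[m]
  bnd <- annotations$at_exon_boundary[m]
  gene <- annotations$gene[m]
  exonic <- c("splice_site", "synonymous", "missense", "stop_gain",
              "stop_loss", "frameshift_indel", "inframe_indel",
              "noncoding_exonic")
  coding <- c("missense", "stop_gain", "stop_loss", "frameshift_indel",
              "inframe_indel", "splice_site")
  af <- if (is.null(freq)) rep(0, length(key)) else {
    a <- unname(freq$af[key]); a[is.na(a)] <- 0; a
  }
  s1 <- cat_ %in% exonic
  s2 <- s1 & (cat_ %in% coding | (cat_ == "synonymous" & bnd))
  s3 <- s2 & if (is.null(db)) TRUE else !key %in% db$keys
  s4 <- s3 & af <= maf_threshold
  s5 <- s4 & if (is.null(panel)) TRUE else gene %in% panel$entries$gene
  list(key = key, sample = calls$sample_id,
       s1 = s1, s2 = s2, s3 = s3, s4 = s4, s5 = s5)
}

# Brute-force coverage recomputation over explicit base grids
coverage_oracle <- function(track, regions, thresholds = c(8, 20)) {
  regions <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  keys <- unlist(lapply(seq_along(regions), function(i) {
    paste(as.character(GenomicRanges::seqnames(regions))[i],
          seq.int(GenomicRanges::start(regions)[i], GenomicRanges::end(regions)[i]))
  }))
  d <- track$depth[match(keys, paste(track$chrom, track$pos))]
  d[is.na(d)] <- 0
  c(median = stats::median(d),
    stats::setNames(vapply(thresholds, function(t) mean(d >= t), 1),
                    paste0("frac_ge_", thresholds)))
}
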