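# The reduction cascade: in-house database, stage semantics, per-stage
# accounting, recurrence, and the soundness/completeness oracle

test_that("build_inhouse_db unions normalized alleles and rejects duplicate samples", {
  d <- withr::local_tempdir()
  v1 <- variant_calls("C01", "1", c(100L, 200L), c("A", "C"), c("G", "T"))
  v2 <- variant_calls("C02", "1", c(200L, 300L), c("C", "G"), c("T", "A"))
  p1 <- file.path(d, "c1.vcf.gz"); write_vcf(v1, p1)
  p2 <- file.path(d, "c2.vcf.gz"); write_vcf(v2, p2)
  db <- build_inhouse_db(c(p1, p2))
  expect_equal(length(db$keys), 3L)  # one shared allele of 3 total
  expect_equal(db$n_samples, 2L)
  p3 <- file.path(d, "c3.vcf.gz"); write_vcf(v1, p3)  # same sample id again
  expect_error(build_inhouse_db(c(p1, p3)), "duplicate sample")
  # empty database is a no-op downstream
  calls <- variant_calls("S1", "1", 100L, "A", "G")
  ann <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                    gene = "GCK", transcript_id = NA, category = "missense",
                    c_name = "", p_name = "", at_exon_boundary = FALSE)
  red0 <- reduce_variants(calls, ann, db = cohort_db(character(), 0L))
  expect_equal(red0$report$rare_population, 1L)
})

test_that("union membership on a simulated cohort equals the brute-force set union", {
  co <- small_cohort()
  d <- withr::local_tempdir()
  sub <- co$calls[co$calls$sample_id %in% c("S01", "S02", "S03"), ]
  paths <- vapply(unique(sub$sample_id), function(s) {
    p <- file.path(d, paste0(s, ".vcf.gz"))
    write_vcf(sub[sub$sample_id == s, ], p)
    p
  }, "")
  db <- build_inhouse_db(paths)
  expect_setequal(db$keys,
                  unique(variant_key(sub$chrom, sub$pos, sub$ref, sub$alt)))
})

test_that("frequency boundary is strict: exactly 0.5% is retained, above is excluded", {
  mk_ann <- function(pos) data.frame(
    chrom = "1", pos = pos, ref = "A", alt = "G", gene = "HADH",
    transcript_id = NA, category = "missense", c_name = "", p_name = "",
    at_exon_boundary = FALSE)
  calls <- variant_calls("S1", "1", c(100L, 200L, 300L), "A", "G")
  ann <- rbind(mk_ann(100L), mk_ann(200L), mk_ann(300L))
  freq <- frequency_resource(data.frame(
    chrom = "1", pos = c(100L, 200L, 300L), ref = "A", alt = "G",
    af = c(0.002, 0.005, 0.0051)))
  red <- reduce_variants(calls, ann, freq = freq, panel = default_panel())
  expect_equal(sort(red$survivors$pos), c(100L, 200L))  # 0.2% and 0.5% kept
})

test_that("stage counts are monotone and match the predicate oracle on a simulated cohort", {
  assets <- small_assets()
  co <- generate_cohort(sim_params(scale = 0.01, n_genes = 40), assets, seed = 21)
  red <- reduce_variants(co$calls, co$annotations, co$db, co$freq, assets$panel)
  r <- red$report
  expect_true(all(r$all_exonic >= r$exonic_coding &
                  r$exonic_coding >= r$not_in_inhouse &
                  r$not_in_inhouse >= r$rare_population &
                  r$rare_population >= r$panel_candidates))
  orc <- reduce_oracle(co$calls, co$annotations, co$db, co$freq, assets$panel)
  # per-sample counts at every stage
  for (stage in c("s1", "s2", "s3", "s4", "s5")) {
    col <- c(s1 = "all_exonic", s2 = "exonic_coding", s3 = "not_in_inhouse",
             s4 = "rare_population", s5 = "panel_candidates")[[stage]]
    exp_counts <- table(factor(orc$sample[orc[[stage]]], levels = r$sample_id))
    expect_equal(r[[col]], as.integer(exp_counts), info = stage)
  }
  # soundness: every survivor passes all predicates; completeness: nothing
  # passing all predicates is missing
  skey <- variant_key(red$survivors$chrom, red$survivors$pos,
                      red$survivors$ref, red$survivors$alt)
  expect_setequal(paste(red$survivors$sample_id, skey),
                  paste(orc$sample, orc$key)[orc$s5])
})

test_that("spiked pathogenic variants are recovered with recall 1.0; empty input gives zero counts", {
  assets <- small_assets()
  co <- generate_cohort(sim_params(scale = 0.02, n_genes = 40), assets, seed = 31)
  co <- spike_pathogenic(co, assets, k = 4, seed = 32)
  expect_equal(nrow(co$truth), 4L)
  red <- reduce_variants(co$calls, co$annotations, co$db, co$freq, assets$panel)
  tk <- paste(co$truth$sample_id,
              variant_key(co$truth$chrom, co$truth$pos, co$truth$ref, co$truth$alt))
  sk <- paste(red$survivors$sample_id,
              variant_key(red$survivors$chrom, red$survivors$pos,
                          red$survivors$ref, red$survivors$alt))
  expect_true(all(tk %in% sk))
  # k = 0 is a no-op
  co0 <- spike_pathogenic(co, assets, k = 0L)
  expect_equal(nrow(co0$calls), nrow(co$calls))
  # empty call set: all stage counts zero
  empty <- co$calls[0, ]
  red0 <- reduce_variants(empty, co$annotations, co$db, co$freq, assets$panel)
  expect_equal(nrow(red0$report), 0L)
  expect_equal(nrow(red0$survivors), 0L)
})

test_that("a spiked mid-exon synonymous variant is not recovered by the cascade", {
  assets <- small_assets()
  co <- generate_cohort(sim_params(scale = 0.01, n_genes = 40), assets, seed = 41)
  # craft a synonymous change in a captured panel gene
  g <- setdiff(assets$panel$entries$gene, assets$absent_genes)[1]
  tx <- assets$models$transcripts[[assets$models$by_gene[[g]][1]]]
  seqs <- cds_sequence(tx, assets$ref)
  codons <- substring(seqs, seq(1, nchar(seqs) - 2, 3), seq(3, nchar(seqs), 3))
  li <- which(substr(codons, 1, 2) == "CT" & seq_along(codons) > 1)[1]
  cp <- (li - 1L) * 3L + 3L
  gpos <- genomic_coordinate(tx, cp)
  b0 <- substr(codons[li], 3, 3)
  b1 <- setdiff(c("A", "C", "G", "T"), b0)[1]
  gref <- if (tx$strand == "+") b0 else chartr("ACGT", "TGCA", b0)
  galt <- if (tx$strand == "+") b1 else chartr("ACGT", "TGCA", b1)
  ann <- classify_variant(tx$chrom, gpos, gref, galt, assets$models, assets$ref)
  expect_equal(ann$category, "synonymous")
  calls <- rbind(co$calls,
                 variant_calls("S01", tx$chrom, gpos, gref, galt,
                               qual = 200, depth = 50))
  anns <- rbind(co$annotations,
                cbind(data.frame(chrom = tx$chrom, pos = gpos, ref = gref,
                                 alt = galt), ann))
  red <- reduce_variants(calls, anns, co$db, co$freq, assets$panel)
  key <- variant_key(tx$chrom, gpos, gref, galt)
  expect_false(key %in% variant_key(red$survivors$chrom, red$survivors$pos,
                                    red$survivors$ref, red$survivors$alt))
})

test_that("unannotated variants abort the cascade with their positions", {
  calls <- variant_calls("S1", "1", c(100L, 200L), "A", "G")
  ann <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                    gene = "GCK", transcript_id = NA, category = "missense",
                    c_name = "", p_name = "", at_exon_boundary = FALSE)
  expect_error(reduce_variants(calls, ann), "unannotated.*1:200")
})

test_that("recurrence summary counts shared variants and genes exactly", {
  mk <- function(s, pos, gene) {
    data.frame(sample_id = s, chrom = "1", pos = pos, ref = "A", alt = "G",
               gene = gene, stringsAsFactors = FALSE)
  }
  # one shared variant
  r <- recurrence_summary(rbind(mk("S1", 100L, "G1"), mk("S2", 100L, "G1")))
  expect_equal(r$n_variants_shared, 1L)
  # same gene, different variants: gene>=2 yes, shared variants none
  r <- recurrence_summary(rbind(mk("S1", 100L, "G1"), mk("S2", 200L, "G1")))
  expect_equal(r$n_variants_shared, 0L)
  expect_equal(r$n_genes_ge2, 1L)
  expect_error(recurrence_summary(mk("S1", 100L, "G1")), "two samples")
  # simulated cohort vs. brute-force tally
  assets <- small_assets()
  co <- generate_cohort(sim_params(scale = 0.05, n_genes = 40), assets, seed = 51)
  red <- reduce_variants(co$calls, co$annotations, co$db, co$freq, assets$panel)
  r <- recurrence_summary(red$rare)
  key <- variant_key(red$rare$chrom, red$rare$pos, red$rare$ref, red$rare$alt)
  tally_v <- rowSums(table(key, red$rare$sample_id) > 0)
  tally_g <- rowSums(table(red$rare$gene, red$rare$sample_id) > 0)
  expect_equal(r$n_distinct_variants, length(tally_v))
  expect_equal(r$n_variants_shared, sum(tally_v >= 2))
  expect_equal(r$n_genes_ge2, sum(tally_g >= 2))
  expect_equal(r$n_genes_ge3, sum(tally_g >= 3))
})

test_that("the printed worked example reduces to its published candidate table", {
  wex <- worked_example()
  expect_gte(nrow(wex$calls) - 14L, 50L)  # at least 50 decoys encoded
  res <- run_worked_example(wex)
  r <- res$reduction$report
  expect_equal(sum(r$panel_candidates), 14L)
  expect_equal(length(unique(res$reduction$survivors$gene)), 12L)
  expect_equal(r$panel_candidates[r$sample_id == "P09"], 4L)
  # stage monotonicity holds on the fixture too
  expect_true(all(r$all_exonic >= r$exonic_coding &
                  r$exonic_coding >= r$not_in_inhouse &
                  r$not_in_inhouse >= r$rare_population &
                  r$rare_population >= r$panel_candidates))
  # oracle agreement on the fixture (well under 1,000 variants)
  orc <- reduce_oracle(wex$calls, wex$annotations, wex$db, wex$freq, wex$panel)
  expect_equal(sum(orc$s5), 14L)
})
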