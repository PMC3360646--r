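# VCF ingestion/writing, allele normalization and the site-level filters

write_text_vcf <- function(lines, path) writeLines(lines, path)

test_that("read_vcf parses genotypes, depth and multi-allelic rows", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_text_vcf(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t50\tPASS\tDP=99\tGT:DP\t0/1:20",
    "1\t150\t.\tC\tA,T\t80\t.\tDP=33\tGT\t1/2",
    "1\t200\t.\tG\tC\t60\t.\t.\tGT:DP\t1/1:12",
    "1\t250\t.\tG\tC\t60\t.\t.\tGT:DP\t./.:9"), f)
  expect_warning(v <- read_vcf(f), "without a usable GT")
  expect_equal(nrow(v), 4L)
  expect_equal(v$chrom, rep("1", 4))           # "chr" prefix stripped
  expect_equal(v$depth[1], 20L)                # per-sample DP beats INFO
  expect_equal(v$depth[2], 33L)                # INFO fallback
  expect_equal(v$genotype[1], "het")
  # ALT "A,T" with GT 1/2 -> two het records at one position
  expect_equal(v$pos[2:3], c(150L, 150L))
  expect_setequal(v$alt[2:3], c("A", "T"))
  expect_equal(v$genotype[4], "hom_alt")
})

test_that("write-then-read is the identity on a simulated multi-hundred-record set", {
  co <- small_cohort()
  one <- co$calls[co$calls$sample_id == "S01", ]
  one <- one[seq_len(min(500L, nrow(one))), ]
  f <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(one, f)
  back <- read_vcf(f)
  std <- function(x) {
    x <- x[order(x$chrom, x$pos, x$alt),
           c("sample_id", "chrom", "pos", "ref", "alt", "qual", "depth",
             "genotype", "filter")]
    rownames(x) <- NULL
    x
  }
  expect_identical(std(back), std(one))
})

test_that("filter flags are mirrored to the FILTER column and survive a round trip", {
  calls <- variant_calls("S1", "1", c(100L, 200L), c("A", "C"), c("G", "T"),
                         qual = c(10, 99), depth = c(5L, 50L))
  calls <- apply_site_filters(calls)
  f <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(calls, f)
  back <- read_vcf(f)
  back <- back[order(back$pos), ]
  expect_equal(back$filter, c("low_depth;low_qual", ""))
})

test_that("SNVs are reference-checked and indels left-aligned to parsimony", {
  ref <- Biostrings::DNAStringSet(c("1" = "GGGCAAAAAATTTTCGCGT"))
  # SNV unchanged
  v <- normalize_variants(variant_calls("S", "1", 4L, "C", "T"), ref)
  expect_equal(v[, c("pos", "ref", "alt")],
               data.frame(pos = 4L, ref = "C", alt = "T"))
  # deletion inside the A-run shifts to the leftmost representation
  v <- normalize_variants(variant_calls("S", "1", 7L, "AAA", "A"), ref)
  expect_equal(v$pos, 4L); expect_equal(v$ref, "CAA"); expect_equal(v$alt, "C")
  # idempotent
  v2 <- normalize_variants(v, ref)
  expect_identical(v2, v)
  # reference mismatch is an error naming the position
  expect_error(normalize_variants(variant_calls("S", "1", 4L, "A", "T"), ref),
               "1:4")
})

test_that("normalization preserves the edited haplotype and is leftmost (random indels)", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  seq <- paste0(seq, "AAAAAATTTTTTCACACA")  # repetitive tail
  ref <- Biostrings::DNAStringSet(c("1" = seq))
  n <- nchar(seq)
  for (i in 1:60) {
    p <- sample(5:(n - 8), 1)
    len <- sample(1:4, 1)
    if (runif(1) < 0.5) {  # deletion
      r <- substr(seq, p, p + len); a <- substr(seq, p, p)
    } else {               # insertion
      r <- substr(seq, p, p)
      a <- paste0(r, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = ""))
    }
    v0 <- variant_calls("S", "1", p, r, a)
    v1 <- normalize_variants(v0, ref)
    # same haplotype
    expect_identical(apply_variant_to_seq(seq, v1$pos, v1$ref, v1$alt),
                     apply_variant_to_seq(seq, p, r, a))
    # brute-force leftmost check: no representation with smaller position
    # produces the same haplotype with parsimonious alleles
    hap <- apply_variant_to_seq(seq, p, r, a)
    if (v1$pos > 1L) {
      shifted_exists <- FALSE
      for (q in 1:(v1$pos - 1L)) {
        for (rl in 0:5) {
          rr <- substr(seq, q, q + rl)
          # candidate alt must reproduce hap given deletion/insertion length
          al <- rl + (nchar(v1$alt) - nchar(v1$ref))
          if (al < 0) next
          aa <- substr(hap, q, q + al)
          # a genuine competitor must itself be parsimonious: its trailing
          # bases differ (no right-trim possible) and, unless one allele is
          # a bare anchor, its leading bases differ (no left-trim possible)
          if (nchar(rr) == rl + 1 && nchar(aa) == al + 1 &&
              apply_variant_to_seq(seq, q, rr, aa) == hap &&
              substr(rr, rl + 1, rl + 1) != substr(aa, al + 1, al + 1) &&
              !(rl >= 1 && al >= 1 &&
                substr(rr, 1, 1) == substr(aa, 1, 1))) {
            shifted_exists <- TRUE
          }
        }
      }
      expect_false(shifted_exists)
    }
  }
})

test_that("depth/quality filters flag below-threshold calls, pass boundaries, and are idempotent", {
  th <- qc_thresholds()
  calls <- variant_calls("S1", "1", c(10L, 20L, 30L, 40L),
                         rep("A", 4), rep("G", 4),
                         qual = c(30, 60, 29.9, 30), depth = c(8L, 7L, 50L, 8L))
  out <- apply_site_filters(calls, th)
  expect_equal(out$filter, c("", "low_depth", "low_qual", ""))
  expect_identical(apply_site_filters(out, th), out)
  # 200 random calls against direct predicate evaluation
  set.seed(1)
  rc <- variant_calls("S1", "1", seq(1000L, by = 50L, length.out = 200L),
                      "A", "G", qual = sample(0:60, 200, TRUE),
                      depth = sample(0:20, 200, TRUE))
  out <- apply_site_filters(rc, th)
  expect_identical(!nzchar(out$filter), rc$depth >= 8 & rc$qual >= 30)
  expect_identical(passing(out), out[rc$depth >= 8 & rc$qual >= 30, ])
})

test_that("SNP-cluster flagging matches the window-enumeration oracle", {
  th <- qc_thresholds()
  mk <- function(pos) variant_calls("S1", "1", pos, "A", "G")
  expect_equal(flag_snp_clusters(mk(c(100L, 105L, 109L)), th)$filter,
               rep("snp_cluster", 3))
  expect_equal(flag_snp_clusters(mk(c(100L, 200L)), th)$filter, c("", ""))
  expect_equal(flag_snp_clusters(mk(c(100L, 109L, 120L)), th)$filter,
               rep("", 3))
  # indels exempt
  v <- rbind(mk(c(100L, 105L)), variant_calls("S1", "1", 109L, "AT", "A"))
  expect_equal(flag_snp_clusters(v, th)$filter, rep("", 3))
  # randomized positions vs oracle; also invariance under row permutation
  set.seed(9)
  for (rep in 1:20) {
    pos <- sort(sample(1:120, sample(5:25, 1)))
    v <- mk(pos)
    out <- flag_snp_clusters(v, th)
    expect_equal(nzchar(out$filter), cluster_oracle(pos, pos),
                 info = paste(pos, collapse = ","))
    perm <- sample(nrow(v))
    out2 <- flag_snp_clusters(v[perm, ], th)
    expect_equal(out2$filter, out$filter[perm])
  }
  # two samples do not cluster jointly
  v <- rbind(variant_calls("S1", "1", c(100L, 105L), "A", "G"),
             variant_calls("S2", "1", 109L, "A", "G"))
  expect_equal(flag_snp_clusters(v, th)$filter, rep("", 3))
})
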