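# Consequence classification against a brute-force codon-translation oracle

test_that("every single-base substitution is partitioned exactly as codon translation dictates", {
  toy <- toy_gene()
  translate_cds <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  aa_ref_full <- translate_cds(toy$cds_seq)
  for (tx in list(toy$tx_p, toy$tx_m)) {
    for (cp in seq_len(tx$cds_len)) {
      g <- genomic_coordinate(tx, cp)
      cod_ref <- substr(toy$cds_seq, cp, cp)
      for (cod_alt in setdiff(c("A", "C", "G", "T"), cod_ref)) {
        gref <- if (tx$strand == "+") cod_ref else chartr("ACGT", "TGCA", cod_ref)
        galt <- if (tx$strand == "+") cod_alt else chartr("ACGT", "TGCA", cod_alt)
        ann <- classify_variant(tx$chrom, g, gref, galt, toy$models, toy$ref)
        # oracle: translate the mutated CDS
        mut <- toy$cds_seq
        substr(mut, cp, cp) <- cod_alt
        aa_mut <- translate_cds(mut)
        ci <- ceiling(cp / 3)
        a0 <- substr(aa_ref_full, ci, ci); a1 <- substr(aa_mut, ci, ci)
        expected <- if (a0 == a1) "synonymous"
          else if (a1 == "*") "stop_gain"
          else if (a0 == "*") "stop_loss"
          else "missense"
        expect_equal(ann$category, expected,
                     info = sprintf("%s c.%d %s>%s", tx$strand, cp, cod_ref, cod_alt))
        expect_equal(ann$c_name, sprintf("c.%d%s>%s", cp, cod_ref, cod_alt))
        if (expected %in% c("missense", "stop_gain", "synonymous")) {
          expect_equal(ann$p_name,
                       sprintf("p.%s%d%s", ifelse(a0 == "*", "X", a0), ci,
                               ifelse(a1 == "*", "X", a1)))
        }
      }
    }
  }
})

test_that("mirrored plus/minus transcripts give identical protein names", {
  toy <- toy_gene()
  set.seed(3)
  for (i in 1:40) {
    cp <- sample(toy$tx_p$cds_len, 1)
    cod_ref <- substr(toy$cds_seq, cp, cp)
    cod_alt <- sample(setdiff(c("A", "C", "G", "T"), cod_ref), 1)
    ann_p <- classify_variant("1", genomic_coordinate(toy$tx_p, cp),
                              cod_ref, cod_alt, toy$models, toy$ref)
    ann_m <- classify_variant("2", genomic_coordinate(toy$tx_m, cp),
                              chartr("ACGT", "TGCA", cod_ref),
                              chartr("ACGT", "TGCA", cod_alt),
                              toy$models, toy$ref)
    expect_equal(ann_m$category, ann_p$category)
    expect_equal(ann_m$p_name, ann_p$p_name)
    expect_equal(ann_m$c_name, ann_p$c_name)
  }
})

test_that("known substitution archetypes classify as expected", {
  toy <- toy_gene()
  tx <- toy$tx_p
  # find a CGG codon-free path: engineer via codon scan on the implanted CDS
  codons <- substring(toy$cds_seq, seq(1, nchar(toy$cds_seq) - 2, 3),
                      seq(3, nchar(toy$cds_seq), 3))
  # TGG -> TGA is a stop gain at codon offset 3
  wi <- which(codons == "TGG")[1]
  if (!is.na(wi)) {
    cp <- (wi - 1) * 3 + 3
    ann <- classify_variant("1", genomic_coordinate(tx, cp), "G", "A",
                            toy$models, toy$ref)
    expect_equal(ann$category, "stop_gain")
    expect_equal(ann$p_name, sprintf("p.W%dX", wi))
  }
  # third-position Leu wobble: CTx -> CTy is synonymous
  li <- which(substr(codons, 1, 2) == "CT")[1]
  cp <- (li - 1) * 3 + 3
  b0 <- substr(codons[li], 3, 3)
  b1 <- setdiff(c("A", "C", "G", "T"), b0)[1]
  ann <- classify_variant("1", genomic_coordinate(tx, cp), b0, b1,
                          toy$models, toy$ref)
  expect_equal(ann$category, "synonymous")
})

test_that("splice-site, intronic, UTR and intergenic classes follow position", {
  toy <- toy_gene()
  tx <- toy$tx_p
  ref <- toy$ref
  at <- function(pos) {
    b <- ref_bases(ref, "1", pos)
    classify_variant("1", pos, b, setdiff(c("A", "C", "G", "T"), b)[1],
                     toy$models, ref)
  }
  don <- tx$exon_ends[1]      # last exonic base (1-based) of exon 1
  expect_equal(at(don + 1L)$category, "splice_site")   # +1 donor
  expect_equal(at(don + 2L)$category, "splice_site")   # +2 donor
  expect_equal(at(don + 3L)$category, "intronic")
  acc <- tx$exon_starts[2] + 1L  # first exonic base of exon 2
  expect_equal(at(acc - 1L)$category, "splice_site")   # -1 acceptor
  expect_equal(at(acc - 3L)$category, "intronic")
  expect_equal(at(110L)$category, "noncoding_exonic")  # 5' UTR base
  expect_equal(at(50L)$category, "intergenic")
  expect_equal(at(590L)$category, "intergenic")
  # widened splice window reclassifies +3
  wide <- classify_variant("1", don + 3L, ref_bases(ref, "1", don + 3L),
                           "A", toy$models, ref, splice_window = 8L,
                           check_ref = FALSE)
  expect_equal(wide$category, "splice_site")
})

test_that("coding indels split into frameshift and in-frame by length", {
  toy <- toy_gene()
  tx <- toy$tx_p
  g <- genomic_coordinate(tx, 30L)
  b <- ref_bases(toy$ref, "1", g)
  b3 <- ref_bases(toy$ref, "1", g, g + 3L)
  # 1-bp insertion: frameshift
  ins1 <- classify_variant("1", g, b, paste0(b, "A"), toy$models, toy$ref)
  expect_equal(ins1$category, "frameshift_indel")
  # 3-bp deletion: in-frame
  del3 <- classify_variant("1", g, b3, b, toy$models, toy$ref)
  expect_equal(del3$category, "inframe_indel")
})

test_that("exon-boundary synonymous changes are splice-relevant; mid-exon ones are not", {
  # engineered plus-strand gene: exon1 1-based 101..109 (9 coding bases:
  # ATG CCA CTT), GT..AG intron 110..189, exon2 from 190 with remaining CDS;
  # the last base of exon 1 is a Leu third position (CTT/CTG wobble)
  set.seed(12)
  lead <- strrep("A", 100)
  ex1 <- "ATGCCACTT"
  rest_codons <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                      c("TAA", "TAG", "TGA")), 20, replace = TRUE),
                       collapse = "")
  ex2 <- paste0(rest_codons, "TAA")
  chrom <- paste0(lead, ex1, "GT", strrep("C", 76), "AG",
                  ex2, strrep("A", 100))
  ref <- Biostrings::DNAStringSet(c("5" = chrom))
  tx <- new_transcript("B-T1", "BND", "5", "+",
                       c(100L, 189L), c(109L, 189L + nchar(ex2)),
                       100L, 189L + nchar(ex2))
  models <- gene_models(list(tx))
  # last base of exon 1 (genomic 109) is third position of Leu codon CTT
  ann <- classify_variant("5", 109L, "T", "G", models, ref)  # CTT->CTG Leu
  expect_equal(ann$category, "synonymous")
  expect_true(ann$at_exon_boundary)
  expect_true(is_reduction_coding(ann$category, ann$at_exon_boundary))
  # a mid-exon synonymous change is dropped
  expect_false(is_reduction_coding("synonymous", FALSE))
  # retention is configurable
  expect_false(is_reduction_coding(ann$category, ann$at_exon_boundary,
                                   keep_boundary_synonymous = FALSE))
})

test_that("is_reduction_coding keeps protein-altering and splice classes only", {
  keep <- c("missense", "stop_gain", "stop_loss", "frameshift_indel",
            "inframe_indel", "splice_site")
  drop <- c("noncoding_exonic", "intronic", "intergenic", "synonymous")
  expect_true(all(is_reduction_coding(keep)))
  expect_false(any(is_reduction_coding(drop)))
})

test_that("reference-mismatch and out-of-frame transcripts are surfaced", {
  toy <- toy_gene()
  g <- genomic_coordinate(toy$tx_p, 10L)
  b <- ref_bases(toy$ref, "1", g)
  wrong <- setdiff(c("A", "C", "G", "T"), b)[1]
  expect_error(classify_variant("1", g, wrong, b, toy$models, toy$ref),
               "reference mismatch")
  suppressWarnings(badtx <- new_transcript("BAD-T1", "BAD", "3", "+",
                                           500L, 600L, 500L, 600L))
  ref3 <- Biostrings::DNAStringSet(c("3" = strrep("ACGT", 200)))
  m <- gene_models(list(badtx))
  expect_warning(ann <- classify_variant("3", 550L, ref_bases(ref3, "3", 550L),
                                         "A", m, ref3, check_ref = FALSE),
                 "out-of-frame")
  expect_equal(ann$category, "noncoding_exonic")
})
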