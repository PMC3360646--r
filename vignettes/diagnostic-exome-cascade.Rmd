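---
title: "Rare-variant reduction and triage for exome-based MODY diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant reduction and triage for exome-based MODY diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomody)
```

## The problem

Maturity-onset diabetes of the young (MODY) is autosomal-dominant monogenic
diabetes. When Sanger sequencing of the usual candidate genes (*HNF1A*,
*HNF4A*, *GCK*, *HNF1B*, *INS*) is negative, exome sequencing offers a wider
net: capture the exome, call variants, and reduce the tens of thousands of
calls per individual down to a handful of candidates in a pre-defined panel
of diabetes-relevant genes. `exomody` implements that workflow as reusable,
tested components: site-level QC, coding-consequence annotation, the
reduction cascade itself, capture/coverage audits, array-concordance QC, and
rule-based pathogenicity triage — together with a seeded simulator that can
generate every input the pipeline consumes.

## The reduction cascade

Starting from QC-passing calls, five nested stages are counted per sample:

1. **All exonic** — variants in exons (including UTR bases) or canonical
   splice sites.
2. **Exonic coding** — protein-altering classes (missense, nonsense,
   stop-loss, coding indels), splice-site variants, and synonymous changes
   only when they sit on the first or last coding base of an exon adjacent
   to a canonical splice site. Mid-exon synonymous and UTR variants drop
   out here.
3. **Not in the in-house database** — exact-allele exclusion against the
   allele set of a local exome cohort (50 exomes in the study design);
   presence-based, with no cohort-frequency threshold, because the
   database's role is to strip platform artifacts and locally common
   alleles.
4. **Rare in the population resource** — drop alleles with population
   allele frequency strictly above 0.5%. The boundary is retained: a
   variant at exactly 0.5% (or the 0.2% *HADH* archetype) survives.
5. **Panel candidates** — intersection with the candidate-gene panel by
   gene symbol.

Counts are monotone non-increasing by construction, and the tests verify
every stage against an independently coded predicate oracle.

Matching between calls, the in-house database and the frequency resource is
on exact normalized alleles (`chrom:pos:ref:alt` after left-alignment and
parsimony-trimming); strand is never flipped, as resources are assumed to be
reference-stranded.

## Site-level QC

Three site filters are applied as *flags* (no record is deleted; downstream
stages consume the flag-free subset):

* depth ≥ 8 reads (per-sample `DP`, falling back to site `DP`),
* site quality `QUAL` ≥ 30 — interpreted as the site-level quality, not
  genotype quality, since the filter set is described per SNP,
* no SNV cluster: an SNV is flagged when any 10-bp window holds ≥ 3 SNVs of
  the same sample. The count defining a cluster is not stated in the
  source design; 3 per window is the convention of standard
  variant-filtration walkers and is exposed as `cluster_count`. Indels pass
  depth/quality filters but are exempt from the cluster rule (the rule is
  stated for SNPs).

Boundary values pass (depth 8, quality 30). All three thresholds are
configurable through `qc_thresholds()`.

## Consequence annotation

Classification precedence is splice site > coding classes > non-coding
exonic > intronic > intergenic. "Canonical splice site" means the two
intronic bases flanking each exon (the GT/AG dinucleotides); the width is
configurable. Substitutions are translated with the standard genetic code on
the coding strand; protein names use a simplified HGVS dialect with `X` for
stop codons (`p.R357X`) and no 3'-rule shifting beyond codon arithmetic.
When several transcripts overlap a variant the longest CDS wins (the
transcript choice is not specified in the source design; one transcript per
gene is the fixture norm).

One genuine irregularity is worth recording: the published *PPARG* pair
c.1071G>A/p.R357X cannot be reproduced by standard codon arithmetic (a
third-position G>A cannot create a stop in an arginine codon); it is almost
certainly a transcript-numbering (isoform) artifact. The package therefore
anchors its codon-arithmetic tests on the *ABCC8* (c.4096/p.A1366) and
*HNF4A* (c.266/p.R89) pairs, uses an engineered TGG→TGA change for
stop-gain testing, and carries the *PPARG* row of the worked example as a
given annotation rather than recomputing it.

## Triage rules

Triage consumes evidence the pipeline does not generate itself: in-silico
predictor verdicts (SIFT, PolyPhen-2, Align-GVGD — the predictors are never
run here), allele frequency in a healthy-control cohort (340 individuals in
the study design), Sanger validation status, and family segregation.

* **Verdict aggregation**: damaging = SIFT `not_tolerated`, PolyPhen-2 ≥
  `possibly_damaging`, Align-GVGD ≥ `C35`. Overall `damaging` requires ≥ 2
  damaging votes among available verdicts (or all of them when fewer than
  two are available), `benign` requires none, otherwise `mixed`;
  with no verdict available the call is `uninformative`. The Align-GVGD cut
  at C35 places a C35 verdict on the damaging side and C15 on the benign
  side, consistent with the worked example's conclusions; it is
  configurable.
* **Segregation**: `does_not_cosegregate` when a tested affected relative
  lacks the variant or a tested unaffected adult carries it (impaired
  glucose tolerance counts as neither); `co-segregates` when at least one
  tested affected relative beyond the proband carries it without
  contradiction; otherwise `uninformative`.
* **Classification cascade**: (i) failed validation → false positive;
  (ii) control frequency > 0.5% → likely benign; (iii) a gene with an
  established dominant-diabetes phenotype plus a truncating consequence or
  an overall damaging verdict, control frequency ≤ 0.5% and uncontradicted
  segregation → pathogenic; (iv) otherwise uncertain.

The published conclusions are expert judgments; this cascade is a documented
reconstruction whose only calibration claim is that it reproduces the worked
example's conclusion column (exactly three pathogenic calls: *ABCC8*,
*HNF4A*, *PPARG*). The control-frequency cutoff separating "likely benign"
from "uncertain" is likewise a reconstruction mirroring the population
filter (no explicit cutoff is published; a 0.1% variant is retained
unclassified while a 1.0% variant draws no pathogenicity conclusion, so any
cutoff in between reproduces the table). The 340-control frequency is
deliberately *not* a reduction stage: it belongs to triage, after
validation, matching the study workflow.

## The synthetic-data generator

`generate_reference_and_genes()` builds a toy genome (a few Mb, three
chromosomes): multi-exon protein-coding genes on both strands with UTRs,
CDS lengths a multiple of 3 translating stop-free, a candidate panel reusing
the diagnostic gene symbols, and capture targets that deliberately omit two
panel genes (*DGKB*, *THADA*) to emulate capture designs missing genes of
interest.

`generate_cohort()` draws per-sample variant sets so that the expected
per-stage survivor counts equal the configured expectations — defaults are
the printed study magnitudes (14,463 exonic; 6,633 coding; 253 after
in-house exclusion; 199 rare; ~2 panel candidates per sample). The design is
a class mixture whose expectations are analytic:

* a shared common coding pool, present in the in-house database, with
  population MAF above 0.5% (Beta-distributed over (0.5%, 50%]);
* a smaller shared pool common in the population resource but absent from
  the in-house database (removed only at the frequency stage);
* shared UTR and mid-exon-synonymous variants (removed at the coding
  stage);
* rare coding variants: 25% from a shared low-frequency pool (0–0.5%,
  driving cross-sample recurrence), 75% private novel alleles; and
* rare coding variants in captured panel genes.

Per-sample class counts are Poisson around these expectations, so the mean
post-frequency count per individual is 199 by construction and the
replicate-mean check in the tests is a genuine distributional recovery, not
a bookkeeping identity. The cohort generator emits its own annotation table
(the consequence labels are part of the sampling design); real-data runs
would instead use `annotate_variants()`, and the spike-in machinery bridges
the two: spiked variants are placed by codon search so that the real
classifier reproduces their intended consequence exactly.

`spike_pathogenic()` injects known-truth het variants (alternating
stop-gain/missense) into captured panel genes, absent from database,
resource and existing calls, with a dominant-segregation family
observation; cascade recall on these is required to be 1.0.
`generate_array_genotypes()` plants het array sites in the capture targets
with an independent per-site detection probability (default 0.91, 7,800
sites, seven samples), so expected concordance equals the detection
probability. `generate_depth_tracks()` draws per-base depths from a gamma
distribution (shape 4) scaled so the theoretical median equals the target
(default 45X), optionally forcing one gene's CDS to near-zero depth.

What the simulation does **not** emulate: read-level error processes,
mapping artifacts, linkage disequilibrium, indel-rich contexts, real allele
frequency spectra, or annotation ambiguity from overlapping transcripts.
Passing tests therefore demonstrate the correctness of the filtering,
accounting and triage logic under the stated statistical design — not
variant-calling performance on real exomes.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; GFF3/VCF (1-based) and
  BED (0-based) are converted at the I/O boundary, and chromosome names are
  normalized (leading "chr" stripped, case-folded) at load time.
* Frequency threshold comparisons are strict (`> 0.005` excludes);
  QC threshold comparisons are inclusive (`>= 8`, `>= 30` pass).
* Region coverage medians over an even base count use the mean of the
  central pair; bases missing from a depth track count as depth 0; per-gene
  coverage is computed over CDS bases (not whole exons), since diagnostic
  sensitivity claims concern coding mutations — configurable by supplying
  other regions.
* Intronic offset ties (equidistant from two exons) resolve to the donor
  side.
* Multi-allelic VCF rows are split before anything else; hom-ref and
  missing genotypes are skipped with a warning.
* Empty inputs: an empty call table reduces to an empty report; an empty
  region set or an empty concordance denominator is an error rather than a
  silent NaN.
* Array concordance defaults to strict allele-aware matching (a hom-alt
  call at an array-het site counts as *not* detected); position-only
  matching is available because either convention is defensible for
  array-vs-sequencing comparisons.

## Problem sizes

The test suite exercises the generator at 1/10 scale (nine samples,
~1,450 exonic variants each, expectations scaled accordingly, ≥ 20
replicate seeds for the calibration check) and a 40–60-gene toy genome; the
acceptance script runs the cohort calibration at full printed scale
(20 replicates of nine samples at ~14,500 variants each) and the array
simulation at its full 7 × 7,800 sites. These sizes are the package's
choices for routine runs; all are parameters of `sim_params()`.

## Known limitations

* HGVS naming is a simplified dialect (no 3'-most shifting of protein-level
  names, no `p.(…)` uncertainty syntax, bare indel c.-names).
* One transcript per gene is assumed throughout the fixtures; the
  longest-CDS rule for overlapping transcripts is a blunt instrument.
* The triage cascade is a reconstruction of expert judgment and should be
  re-tuned before any clinical use.
* The in-house database is presence-based; a frequency-aware local
  database would behave differently for recurrent local artifacts.
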