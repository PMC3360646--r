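# exomody

Exome-based rare-variant diagnostics for monogenic diabetes (MODY), as a
tested R package plus a small analysis workflow.

When Sanger sequencing of the classical MODY genes (*HNF1A*, *HNF4A*,
*GCK*, *HNF1B*, *INS*) is negative, exome sequencing widens the search: call
variants genome-wide, then reduce ~14,000 exonic variants per individual to
a handful of candidates in a pre-defined panel of diabetes genes, and triage
those candidates with predictor verdicts, control-cohort frequencies and
family segregation. `exomody` implements that workflow for analysts working
on gene-panel diagnostics: each step is a documented function, every step is
tested against independent oracles, and a seeded simulator generates
complete synthetic cohorts so the whole pipeline can be validated end to
end without patient data.

## The method

Per sample, QC-passing variant calls pass through five nested filters, with
per-stage accounting:

| stage | keeps | default |
|---|---|---|
| S1 all exonic | exonic (incl. UTR) + canonical splice sites | — |
| S2 coding | missense, nonsense, stop-loss, coding indels, splice-site; synonymous only at exon-boundary bases | splice window ±2 bp |
| S3 in-house | alleles **not** seen in a local exome cohort (exact-allele) | 50 exomes |
| S4 rare | population allele frequency ≤ threshold (strictly `>` excluded) | MAF 0.5% |
| S5 panel | variants in candidate-panel genes | 25-gene default panel |

Upstream, site-level QC flags calls with depth < 8, site quality < 30, or
SNVs in clusters (≥3 SNVs in any 10-bp window). Downstream, each panel
candidate is triaged by a rule cascade over validation status, control
frequency (n = 340), aggregated SIFT/PolyPhen-2/Align-GVGD verdicts
(damaging = `not_tolerated` / ≥ `possibly_damaging` / ≥ C35, majority of
available verdicts) and family segregation, into
pathogenic / uncertain / likely benign / false positive.

Coverage auditing (median depth, fraction of bases ≥8X/≥20X, per-gene CDS
coverage, panel genes absent from the capture design) and heterozygous
array-vs-sequencing concordance round out the QC side.

## Worked example

The package ships an encoder for a published worked example: 14 rare
candidate-panel variants found across nine probands, plus 70 decoy variants
(population-common, in-house, mid-exon synonymous, intronic/UTR, off-panel)
that the cascade must remove.

```r
library(exomody)
res <- run_worked_example()
res$reduction$report
#>   sample_id all_exonic exonic_coding not_in_inhouse rare_population panel_candidates
#>   P01 ... P09 with panel_candidates  1 2 3 1 2 0 1 0 4
table(res$triage$triage_class)
#> excluded_false_positive  likely_benign  pathogenic  uncertain
#>                       1              1           3          9
res$triage$gene[res$triage$triage_class == "pathogenic"]
#> "ABCC8" "PPARG" "HNF4A"
```

14 variants in 12 genes survive the cascade (4 in proband P09); one is
excluded as a Sanger-validation false positive, one is likely benign at
1.0% control frequency, and exactly three — the *ABCC8* p.A1366T missense,
the *HNF4A* p.R89Q missense and the *PPARG* p.R357X nonsense — are classed
pathogenic.

## Analysis workflow

`analysis/` holds numbered drivers that exercise the package on a 1/10-scale
synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # toy genome + 9-sample cohort + spike-ins
Rscript analysis/02_reduce.R          # reduction cascade, recurrence, recall
Rscript analysis/03_coverage.R        # coverage summaries, absent panel genes
Rscript analysis/04_concordance.R     # simulated 7,800-SNP array concordance
Rscript analysis/05_worked_example.R  # the published worked example
```

## Layout

* `R/` — package code: gene models and coordinate arithmetic, VCF I/O and
  normalization, site QC, consequence annotation, the reduction cascade,
  panel/coverage, concordance, triage, the synthetic-data generator, the
  worked-example encoder, report writers.
* `tests/testthat/` — unit and property tests (brute-force oracles for
  normalization, clustering, reduction, coverage and codon translation).
* `vignettes/diagnostic-exome-cascade.Rmd` — the methods vignette: model,
  parameters, generator design, numerical choices, limitations.
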