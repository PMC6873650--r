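# tevr

Polymorphic transposable-element variants (TEVs) and their effect on
flanking-gene expression.

The three transposable-element classes still active in the human genome —
Alu, LINE-1 (L1) and SVA — keep generating structural variants that
segregate among individuals. Because TE-derived sequence frequently carries
regulatory function, a polymorphic insertion near a gene can shift that
gene's expression. `tevr` implements the full analysis chain used to study
this question in a population cohort with matched genotypes (an MEI VCF
catalog) and RNA-seq expression (a gene × sample RPKM table): catalog
filtering, cis-eQTL scanning with randomization validation, genome-wide and
regulatory-region enrichment tests, orientation and genomic-context
analyses, karyotype-band density ranking, and matching of RNA-seq-derived
insertion calls to DNA variants. A seeded synthetic-data generator with
known ground truth makes every stage testable end to end without any
external download.

The package is written for analysts working with population genomics +
transcriptomics data: every user-facing function takes a data frame and
returns a tibble, results compose with the pipe, fitted objects have
`tidy()` / `glance()` methods, and each result type has a plot function.

## The model

For each cis pair — a variant *v* and a gene *g* on the same chromosome
whose interval distance is strictly below 1 Mbp — the scan fits the
additive least-squares model

```
y_gs = μ + β g_vs + a·1{male_s} + Σ_k b_k·1{pop_s = k} + ε_s
```

where `y_gs` is the RPKM expression of gene *g* in sample *s* and
`g_vs ∈ {0, 1, 2}` counts TE-**presence** alleles (deletion-coded `*_DEL`
records, where the element is absent from the reference, are recoded as
`2 − ALT count` so effect signs are comparable across both encodings).
The per-pair statistic is `t = β̂ / SE(β̂)` with a two-sided p-value on
`n − p` degrees of freedom; Benjamini–Hochberg FDR is applied jointly over
all tested pairs and associations with `q ≤ 0.05` are called significant.
The scan is validated by genotype randomization: each variant's dosage
vector is permuted independently `R = 100` times, the scan re-run, and the
observed significant count compared with the randomized counts as
`z = (observed − mean)/sd`.

Enrichment analyses use the same randomization logic on coordinates:
features are counted in 10 Mbp windows sliding by 5 Mbp (or in regulatory
vs non-regulatory sequence, or karyotype bands) and compared with random
placements of the same number and length; `|z| > 3` is called
enriched/depleted. RNA-seq insertion calls support a DNA variant when they
are of the same class, in the same individual (who must carry the variant
at DNA level) and strictly less than 50 bp away.

## Worked example

A full synthetic run at cohort size 200 (the generator defaults emulate the
study design: 5 populations, a three-class catalog with rare variants down
to the 3-carrier floor, a 15% deletion-coded fraction, 20 planted cis
effects of ±1.5 expression units among ~1,900 cis pairs):

```r
library(tevr)
cfg <- tev_config(n_samples = 200, seed = 42)
run <- run_tev_pipeline(cfg)
run
#> tevr pipeline run (seed 42 )
#>   variants: 485 read, 474 after carrier filter
#>   cis-eQTL: 1864 pairs tested, 22 significant
#>   RNA-TEVs: 7 matched, 1 in eQTL set

run$permutation
#> Genotype-randomization validation: observed 22 significant vs null mean
#> 0.1 (sd 0.27), z = 80.39, empirical p = 0.0099 (R = 100)

run$class_summary
#> # A tibble: 3 × 4
#>   te_class total filtered significant
#> 1 Alu        400      390          15
#> 2 L1          60       59           4
#> 3 SVA         25       25           3

head(dplyr::arrange(tidy(run$scan), q_value), 3)
#> # A tibble: 3 × 11 (columns abridged)
#>   variant_id gene_id   beta     se  p_value  q_value
#> 1 L1_00446   GENE0248  1.69 0.0938 3.44e-43 6.42e-40
#> 2 L1_00402   GENE0117 -1.67 0.100  4.11e-39 3.83e-36
#> 3 SVA_00476  GENE0068 -1.54 0.0977 1.19e-36 7.37e-34
```

Reading: the catalog filter kept 474 of 485 variants with ≥ 3 carriers; the
scan recovered the planted effects (estimated β̂ near the true ±1.5, tiny
q-values) plus the occasional borderline null pair, and the randomization
null — mean 0.1 significant associations per permuted scan — places the
observed count 80 standard deviations above chance. `tev_report(run)`
prints the consolidated section tables (per-class summary, top enriched
windows, regulatory Z table, orientation table, band-density ranking,
RNA-TEV summary); `autoplot(run$scan)`, `plot_window_enrichment()`,
`plot_presence_heatmap()` and friends draw the standard figures.

Real data in the standard formats (MEI VCF, RPKM TSV, GTF/BED annotation,
UCSC cytoBand, MELT-style call tables) run through the same functions via
`run_tev_pipeline(cfg, input_dir = ...)` or the individual readers.

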