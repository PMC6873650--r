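---
title: "Methods: TEV catalogs, cis-eQTL scanning and enrichment randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TEV catalogs, cis-eQTL scanning and enrichment randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`tevr` analyses polymorphic transposable-element variants (TEVs) of the
three classes active in the human genome (Alu, L1, SVA) together with
matched expression data. This vignette documents the statistical model,
the analysis conventions and the numerical choices, and what the
synthetic-data generator does and does not emulate.

# The catalog and its conventions

A variant table holds one row per TEV with class, strand, length, a
deletion-coding flag and per-sample dosages. Two conventions matter
throughout:

**Dosage counts TE presence.** MEI catalogs contain both insertion records
(the element is absent from the reference and present in carriers' ALT
allele) and deletion-coded records (`ALU_DEL`, `LINE1_DEL`, `SVA_DEL`): the
element sits in the reference and the ALT allele marks its *absence*. The
reader recodes deletion-coded genotypes as `2 − ALT count` so that every
dosage counts TE-presence alleles. This is a deliberate design choice: the
alternative (regressing on raw ALT counts) would flip the sign of every
deletion-coded effect and make effect sizes incomparable across the two
encodings. The recoding is involutive, so writing and re-reading a catalog
is lossless.

**Coordinates are 0-based half-open internally.** GTF (1-based closed) is
shifted on input, BED and cytoBand pass through, and VCF positions stay
1-based in the `pos` column of the variant table. The converters live only
in readers and writers; all interval arithmetic (overlap, distance,
tiling) happens in the internal convention, implemented on
GenomicRanges/IRanges.

**Carrier-based inclusion.** The catalog filter keeps variants carried
(dosage ≥ 1) by at least 3 individuals. We interpret "present in at least
3 individuals" as a *carrier* count, not an allele count, because the
implied minimum frequency arithmetic (3 of 445 → 0.7%) is carrier-based.
Missing genotypes stay missing at catalog level and are dropped per pair
at fit time; no imputation is attempted, which is unbiased under
missingness unrelated to genotype.

# The cis-eQTL scan

For a variant–gene pair the model is ordinary least squares of expression
on `[intercept, dosage, sex dummy, K−1 population dummies]`. Expression is
fitted on the raw RPKM scale by default because that is the scale the
upstream tables provide; a `log2(x+1)` mode (`expression_log2`) exists for
sensitivity checks. Pairing is *cis*: the distance between the variant
locus and the **gene interval** must be strictly below 1 Mbp. We anchor at
the gene body rather than the TSS because the pairing rule is stated in
terms of gene-to-variant distance; distances are 0 for intra-genic
variants, and deletion-coded variants use their full deleted-element
interval while point insertions use a 1 bp locus.

Numerically the scan residualizes expression and dosage against the
covariate design once (QR decomposition) and fits each pair as a simple
regression of residuals — algebraically identical to the full OLS fit
(Frisch–Waugh), with standard errors on the full-model residual degrees of
freedom. The test suite verifies this equivalence against a closed-form
normal-equations oracle at 1e-8 relative tolerance. Pairs with missing
dosages drop the affected samples and fall back to a direct QR fit.

Degenerate pairs are skipped with a recorded reason rather than fitted:
`monomorphic` (constant dosage after missing-removal), `collinear`
(dosage in the span of the covariates; detected as residual dosage energy
below `1e-10 · n`), `insufficient_samples`. A zero-residual fit (possible
in noiseless simulations) reports `p = 0` with a `perfect_fit` flag
instead of failing.

Multiplicity: Benjamini–Hochberg over **all tested pairs in one family**,
with significance at `q ≤ 0.05`. BH is the standard choice of the eQTL
tooling this workflow mirrors; skipped pairs are excluded from the family.
The implementation wraps `stats::p.adjust(method = "BH")` behind the
package's `bh_adjust()` surface, and a property test checks it against the
step-up definition written out directly.

**Genotype-randomization validation.** Each variant's dosage vector is
permuted independently across samples (expression and covariates
untouched), the scan re-run, and the number of significant associations
recorded; over `R = 100` replicates the summary is
`z = (observed − mean)/sd` with the sample (n−1) standard deviation and an
empirical p with a +1 pseudocount, `(1 + #{reps ≥ obs})/(1 + R)`, so p is
never exactly 0 at finite R. Per-variant permutation breaks variant–variant
LD deliberately: it randomizes each genotype vector literally, which is the
stated scheme; the null therefore answers "how many associations would
this many unrelated genotype vectors produce", not "how many would a
LD-preserving rotation produce". When the replicate counts are constant
(sd = 0), z is reported as ±Inf (or 0 on equality) with a flag rather than
NaN.

# Enrichment randomization

**Sliding windows.** The genome is tiled into 10 Mbp windows sliding by
5 Mbp; windows start at multiples of the step while the start is inside
the chromosome, and terminal windows are clipped to the chromosome end.
Clipped windows are *kept*: because the randomized placements are counted
over the identical window list, their Z-scores remain comparable. Features
are counted in every window they overlap (half-open test), so an interior
point lands in exactly `width/step` windows.

**Coordinate randomization** preserves the feature-length multiset
exactly; each feature is re-placed uniformly on the genome with the
chromosome drawn proportionally to its placeable length (length − feature
length + 1) and the feature fully inside. Randomization is genome-wide
(the shuffling idiom of the workflow this mirrors); a per-chromosome
variant can be obtained by calling `randomize_coordinates()` per
chromosome. Per-window enrichment reports z (sample sd over R
randomizations — the n−1 convention, documented because the alternative
population-sd choice is equally defensible), the pseudocounted empirical
p, `−log10 p` for Manhattan-style plotting, and BH q over windows;
`z > 3` is called enriched.

**Regulatory regions** use the same machinery with the observed statistic
being the *percentage* of a class's variants overlapping any regulatory
interval. Overlap is any-overlap, not bp-fraction — the simplest rule
consistent with intersect-style workflows; `z > 3` / `z < −3` mark
enrichment/depletion of the class in regulatory and (complementarily)
non-regulatory sequence.

**Karyotype bands** are ranked by overlap count normalized by band length
(count per bp), optionally per group (e.g. tissue) with per-group ranks.

# Orientation and genomic context

Intra-genic variants are concordant when their strand matches the host
gene's transcribed strand. A variant overlapping genes on both strands is
counted once, as concordant if *any* same-strand gene overlaps — a
deterministic rule for a case the analysis definition leaves open (a few
percent of variants in simulations). Unknown-strand variants are excluded
into an `unoriented` bucket. Class differences are tested with two-sided
Fisher exact tests on (concordant, discordant); Fisher p-values are
computed by `stats::fisher.test`, i.e. summation of hypergeometric
probabilities not exceeding the observed table's probability, and the test
suite cross-checks this against a direct summation oracle at 1e-10.

Context classification labels each variant by the substructure feature it
overlaps with precedence `3'UTR > 5'UTR > exon > intron`, `intergenic`
otherwise. UTRs outrank generic exon because UTR categories are reported
separately from exons; within a gene span, unannotated gaps count as
introns (this also makes BED-only annotations behave sensibly: every
intra-genic variant becomes intronic). The labels partition any variant
set, which is asserted in tests.

# RNA-supported variants

An RNA-seq-derived insertion call supports a DNA variant iff same
chromosome, same class, point-to-point distance **strictly** below 50 bp,
and the call's sample carries the variant at DNA level (dosage ≥ 1). The
carrier requirement is stricter than "identified in the same individual"
alone but is the only reading under which the DNA and RNA evidence refer
to the same allele. Distances compare insertion point estimates, not
interval boundaries. When several variants lie within the radius the call
is assigned to the nearest, ties broken by the lower variant coordinate —
a deterministic rule for a collision case the matching definition does not
address. Downstream summaries: per-class `log2(%RNA / %all)` composition
ratios (−Inf flagged when a class is absent), a population-grouped binary
presence matrix over DNA carriers, genomic-context and gene-biotype
comparisons reusing the classifier above, and the overlap flag against the
significant eQTL set.

# The synthetic-data generator

The generator emulates the study design so that every pipeline stage runs
on data with known ground truth:

* a cohort of 445 individuals (default) from 5 populations with sex
  recorded;
* a three-class catalog with the Alu-dominated class imbalance of human
  MEI catalogs, scaled down
  (defaults 400 Alu / 60 L1 / 25 SVA on a 150 Mbp three-chromosome toy
  genome, giving roughly 2,000 cis pairs at the 1 Mbp window — the scale
  all calibration tests use), Hardy–Weinberg genotypes over a MAF mixture
  with a rare tail (35% of variants uniform below 5% down to the 0.5%
  floor, the rest uniform up to 0.5), ±-strand annotation and a 15%
  deletion-coded fraction;
* expression `y = μ_g + a_g·male + b_{g,pop} + Σ β·dosage + ε`, `ε ~
  N(0, σ²)`, clipped at 0 (RPKM are non-negative), with log-normal
  baselines (median ≈ 10) and Gaussian per-gene covariate effects
  (sd 0.5 expression units each). Planted cis effects default to 20 pairs
  of |β| = 1.5 at σ = 1. Effects are planted only on variants with MAF ≥
  5% (`planted_min_maf`): ground-truth recovery checks need identifiable
  effects, and the rare tail intentionally stays null;
* gene models laid non-overlapping with 5'UTR/exon/intron/3'UTR
  substructure (UTRs at the transcript ends given the strand) so context
  classification is exercised, plus regulatory intervals (~8% of the
  genome) and a karyotype-band table;
* RNA calls from a transcribed subset of variants (default 1.5%,
  mirroring the observed scale of transcribed TEVs relative to a full
  catalog): per carrier a call with probability `rna_tp_rate` at the
  variant position plus uniform jitter within ±(`rna_jitter`−1) bp,
  plus false calls at random positions/classes at a configured rate, with
  per-call truth labels returned.

Everything is deterministic given one global seed, which fans out to fixed
per-stage child seeds so stages can be re-run in isolation;
`write_fixture_bundle()` emits the whole set in the exact file formats the
readers consume (byte-identical across runs at the same seed).

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: linkage disequilibrium between variants (each
genotype vector is drawn independently), population-differentiated allele
frequencies (population labels affect expression, not genotypes, except
where a test plants stratification explicitly), sequence-level artefacts
(no FASTQ/alignment, so the RNA-call error model is positional jitter plus
uniform false calls, not mapping bias), expression count noise
(Gaussian on the RPKM scale, not negative-binomial), and genome structure
(uniform variant placement, no hotspots unless planted).

# Problem sizes and thresholds

All thresholds are config keys defaulting to the analysis constants:
minimum carriers 3, cis window 1 Mbp, FDR 0.05, enrichment |Z| 3,
randomizations R = 100, RNA matching radius 50 bp, windows 10/5 Mbp. The
calibration tests run at the sizes the checks are defined for: OLS-oracle
agreement on 500 random pairs of n ≤ 50; false-discovery behaviour over
50 global-null cohorts of n = 200 (~1,900 tested pairs each);
planted-effect recovery and permutation validation on the n = 200 bundle
with R = 100; window calibration on a 240 Mbp three-chromosome genome with
2,000 uniform features. These sizes are the package's chosen operating
points for its own verification, balancing Monte-Carlo resolution against
a test suite that stays fast enough to run routinely.

# Known limitations

* The per-variant permutation null ignores LD, so on real data the
  randomization mean understates the correlation structure of the catalog.
* Raw-scale RPKM fitting is what the upstream tables provide, but
  heteroskedasticity across expression levels means p-values on real data
  are approximate; the `log2` mode is the robustness check.
* Any-overlap regulatory statistics weight a 300 bp Alu and a 6 kb L1
  equally; a bp-fraction variant would need a different observed statistic.
* The band-density ranking normalizes by band length only, not by gene
  content or SNP density, so it measures density, not enrichment beyond
  gene density.
* Catalog bookkeeping of the extended-set counts is taken as given from
  the upstream VCF; the reader validates classes and genotypes but does
  not re-call variants.
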