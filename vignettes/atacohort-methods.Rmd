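---
title: "Methods: cohort-scale chromatin accessibility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-scale chromatin accessibility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atacohort)
```

# Scope

`atacohort` implements a complete cohort-scale ATAC-seq analysis: from
per-sample peak calls and fragments to a consensus region map, a
quantile-normalised accessibility matrix, cohort variability statistics and
corridor tracks, differential-variability testing between disease subtypes,
patient-aware cross-validated subtype classification with data-driven
signature extraction, clustering/PCA for intermediate-subtype discovery, and
footprint-based gene-regulatory-network inference with differential
connectivity. A synthetic cohort generator reproduces the statistical
structure such a study rests on, so the whole pipeline is testable without
patient data. Read alignment, peak calling and footprint detection are
upstream of this package: it consumes their standard outputs (BED intervals,
footprint tables with purity scores).

# The consensus map

Per-sample peaks are merged into their interval union (`merge_peak_sets()`).
Coordinates are BED-style 0-based half-open throughout, and book-ended
intervals (end of one equals start of the next) merge, matching the default
behaviour of the standard interval-merge utilities. Saturation analysis
(`saturation_curve()`) adds samples in random order and reports, per step,
the mean number of distinct merged regions with a 2.5/97.5 percentile band
across orderings; we use the percentile band because a parametric interval
assumes a sampling model the permutation design does not provide.

Region support is the fraction of samples with a called peak overlapping the
region. The class boundaries are conventions and are therefore recorded in
the output: constitutive means support above 0.95; rare means support at or
below 0.05 *or* a single supporting sample (so the class keeps its meaning in
small cohorts); everything between is shared.

Nearest-TSS annotation measures the distance from the region midpoint (not
the edge) to the TSS, zero when the TSS falls inside the region, with ties
broken towards the lexicographically smallest gene identifier. Midpoint
distance is symmetric under strand and region growth; the choice is recorded
in the outputs.

# The accessibility matrix

`quantify_regions()` counts, per region and sample, the fragments
overlapping the region by at least one base (half-open overlap). A fragment
touching several regions counts in each; this keeps the column sums equal to
the number of overlap events, a conservation law the tests assert.

Quantile normalisation follows the classical construction: the reference
distribution is the row-wise mean of the column-sorted matrix and each
column's values are replaced by the reference values at their ranks. Ties
within a column receive the mean of the reference values at the tied rank
positions. The implementation is deliberately our own few lines rather than a
wrapper, because the tie rule is part of the package contract; the tests
cross-check it against an independent implementation (limma) on tie-free
input and assert idempotence.

Variability statistics per region are the across-sample mean, standard
deviation (n−1), variance-to-mean ratio and squared coefficient of
variation. Gene-level summaries use two deliberately disjoint distance
classes: the promoter value is the closest region within 1,000 bp of the
TSS, the distal value is the mean of regions beyond 2,500 bp; regions in the
1,000–2,500 bp gap belong to neither (the two stated rules do not cover
them, and we do not invent a third).

Corridor tracks summarise depth-normalised per-base coverage (reads per ten
million filtered reads, `value / total * 1e7`) across the cohort: the mean
plus the 5th, 25th, 75th and 95th percentiles, computed with linear
interpolation between order statistics (R's type-7 quantile; recorded in the
track metadata). Positions where some samples have zero coverage contribute
their zeros. Corridors are computed over requested loci rather than
genome-wide by default, which keeps the computation desk-scale; the
bedGraph emitter writes one track per statistic.

# Subtype analysis

Samples are labelled by IGHV germline homology: strictly above 98% is
unmutated, at or below is mutated, missing is unknown and excluded.

**Differential variability.** Per region, an F test of equal group
variances: `F = s²(mutated) / s²(unmutated)` with a two-sided p-value
`2·min(P(F≥f), P(F≤f))` capped at one, Bonferroni-corrected over the
regions actually tested (zero-variance-in-both regions are skipped and do
not enter the denominator, which is recorded). A region is called
significant when the corrected p-value is below 0.05 and its overall mean
accessibility exceeds 1, and significant regions are split by which group
carries the larger variance. A caveat the package states openly: the F test
assumes normality, and on overdispersed count data its extreme tail is
anticalibrated, so the Bonferroni guarantee should not be over-read on raw
or quantile-normalised counts; our null-cohort simulations quantify this and
the limitation section returns to it.

**Patient-aware cross-validation.** A random forest predicts the subtype
from the normalised matrix, evaluated by leave-one-out cross-validation in
which every training set excludes all samples from the test sample's
patient — the leakage contract is asserted programmatically in the tests.
Out-of-fold class-probability scores are pooled into a single ROC curve; the
AUC equals the Mann–Whitney concordance probability with ties counted one
half, and the reported operating point is the ROC point closest (Euclidean
distance) to the top-left corner.

The ensemble configuration is open in the method definition, so the package
fixes and documents its own defaults (`rf_config()`): 500 trees, `sqrt(p)`
candidate features per split, terminal nodes of at least 10 observations
(the standard probability-forest default, which keeps class probabilities
calibrated), plus two deliberate choices that exist because pooled
leave-one-out ROC curves compare scores produced by different training
sets. First, each tree draws a class-balanced bootstrap: holding out a
sample depresses its own class's training prevalence, which pushes its
score down and deflates the pooled AUC below the theoretical 0.5 under
label permutation (roughly 0.39 at 40 samples with a plain bootstrap, in
our measurements). Second, every fold's score is re-centred by the
training set's out-of-bag mean score (then clamped to `[0, 1]`), removing
the residual fold-level score offset that even the balanced bootstrap
leaves behind (null means around 0.43–0.47 without it at n = 40). With
both in place the shuffled-label null (`shuffled_label_null()`) averages
to its theoretical 0.5 within Monte-Carlo error, which is the precondition
for reading the null distribution at all. Under genuine signal the fold
offset is close to constant, so calibration leaves the ranking — and the
AUC — essentially untouched. Both behaviours are configuration flags, not
hard-wired.

**Signature extraction.** Gini (impurity-decrease) importances are
normalised to sum to one within each fold — putting them on the scale of
the common Python implementation, where the conventional 10⁻⁴ threshold
originates — then averaged over folds; regions above the threshold form the
signature, with a direction assigned by comparing group means (cluster 1:
more accessible in mutated; cluster 2: more accessible in unmutated).

**Intermediate subtypes.** Samples are clustered on their signature-region
profiles with average-linkage hierarchical clustering on one minus the
Pearson correlation, cut at a configurable k (default 4). PCA
(`pca_projection()`) is a centred SVD of the samples-by-regions matrix.

# Regulatory networks

Footprint sites pass a two-part filter: purity strictly above 0.7 and
overlap with an accessible peak; a TF is kept only with at least 500
qualifying sites (both thresholds configurable). Sites are assigned to
genes: inside a gene body or within 2,500 bp upstream of a TSS
(strand-aware) they attach to that gene — to every such gene when models
overlap, each receiving full weight (no splitting; flagged in metadata) —
and intergenic sites go to the gene with the nearest TSS by site-midpoint
distance, ties again lexicographic.

The interaction score between TF t and gene g is additive over the assigned
sites: each site contributes `2·(P − 0.5) · 10^(−d / 10⁶)`, where P is its
purity and d its midpoint-to-TSS distance in bp. The purity term vanishes at
the chance level 0.5 and reaches one for a perfect site; the distance term
decays tenfold per megabase. The functional form is our declared choice: the
method this follows describes a purity- and distance-weighted sum without
fixing the exact expression, so both the purity transform and the decay
constant are configurable arguments and the form used is recorded in the
score attributes. Edges are pairs with score strictly above 1; differential
connectivity divides each node's degree by its network's total edge count
(compensating for global size differences), takes log2 ratios for nodes
present in both networks, and reports single-network nodes separately. A
"more than 200 connections" display filter exists as a reporting flag only
and never enters the statistics.

# The synthetic cohort generator

The generator (`cohort_spec()`, `generate_cohort()`) is first-class,
tested code, and its defaults define the study conditions used throughout
the tests: 40 samples from 25 patients (so some patients contribute several
samples and the leakage contract is exercised), a 2,000-region universe
(1,500 core regions present in every sample, 300 variable regions present
in random subsets, 5 private regions per sample), two subtypes at equal
patient proportions with IGHV homologies drawn on either side of 98%, 50
signature regions with a ±1.5/2 log2 shift per group (the group log2
difference equals 1.5), and 50 diff-var regions with a variance ratio of 4
at an unchanged mean.

Counts are negative binomial in the mean/dispersion parameterisation with a
cohort-average accessible-state mean of 10 and dispersion 0.2 — the
overdispersion range typical of bulk count data. Each region additionally
receives its own baseline drawn once from a mean-preserving lognormal
(log-sd 0.5) shared by all samples. This per-region profile is what makes
sample-to-sample correlations meaningful: with a flat baseline, the
correlation between two samples over a region set is driven by noise alone,
and correlation-based clustering (including the intermediate-subtype
analysis) would be degenerate in a way real data never is. Diff-var
planting scales the dispersion of the higher-variance group to
`r·φ + (r−1)/μ`, which achieves the requested variance ratio r at an
unchanged mean, so planted variance differences are not confounded with
mean shifts. Intermediate samples get the arithmetic midpoint of the two
subtype means at signature regions and homology values straddling 98%.

Fragments are placed so that counting them over the region universe
reproduces the drawn count matrix exactly — the quantification stage can
therefore be tested against the generator's own ground truth — and
per-sample fragment totals are recorded as total filtered reads. Footprint
purities live on (0.5, 1] (a Beta draw rescaled), since purity is a
confidence-like score whose operative threshold is 0.7. Planted TF→gene
pairs receive many high-purity promoter-proximal sites; decoy pairs receive
a single weak qualifying site; decoy TFs carry a quarter of a retained TF's
site count so they fall below the site-count filter at any calibration.
Background sites avoid the neighbourhoods of planted and decoy genes so the
planted/decoy contrast stays interpretable.

What the generator does *not* emulate: mappability and GC biases, peak
width variation, chromosome-scale covariance (copy-number effects), clonal
heterogeneity within patients, or footprint shape. Passing tests therefore
demonstrate the correctness and statistical behaviour of the algorithms
under a clean overdispersed-count model, not robustness to every artefact
of real sequencing data.

# Numerical choices and problem sizes

All randomness flows from one integer seed; per-fold and per-permutation
seeds are derived arithmetically (kept below 2³¹), so every result is
bit-reproducible. Regeneration of a cohort from the same spec is
bit-identical, and the pipeline's run summary stores the config hash, seed
and input checksums needed to reproduce any artefact.

The shipped simulations are sized for a desk: the default cohort is 40 × 2,000,
the shuffled-label null uses 100 permutations (the analysis of a real cohort
would typically use 1,000), saturation uses 100–1,000 orderings, and the
null-calibration study uses 100 cohorts of 500 regions. These sizes are
choices, not limits; every count is an argument.

# Known limitations

* The F test's family-wise error control is nominal under normality only.
  On negative-binomial counts — including after quantile normalisation —
  its far tail is anticalibrated and the Bonferroni guarantee degrades;
  our null-cohort simulations make this visible rather than hiding it. A
  rank- or resampling-based variance test would be the robust alternative
  and is out of scope here because the implemented method is the classical
  F test.
* With a variance ratio of 4 and 30 samples per group, the per-region power
  of the Bonferroni-corrected F test is modest once thousands of regions
  are tested (exact computation via the F quantile function gives roughly
  23% at 2,000 regions); detecting most planted diff-var regions at that
  effect size is mathematically out of reach at cohort scale, and the
  package reports what the test can actually deliver.
* Pooled leave-one-out ROC curves are intrinsically sensitive to
  cross-fold score comparability; the balanced bootstrap and per-fold
  calibration address the two identifiable mechanisms, and the null
  distribution the package computes is the honest reference for whatever
  residual effect remains.
* The interaction-score weight is a declared stand-in for a formula the
  method family describes only qualitatively; all constants are exposed and
  recorded in outputs.
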