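# atacohort

Cohort-scale chromatin accessibility analysis in R.

ATAC-seq profiling of large patient cohorts — dozens of samples, several per
patient — raises analysis questions that single-sample tooling does not
answer: how do per-sample peak calls combine into one coordinate frame, how
fast does that frame saturate as samples accrue, which regions vary across
the cohort and which vary *differently* between disease subtypes, can the
subtype be predicted from chromatin alone without leaking information
between samples of the same patient, and what do transcription-factor
footprints say about regulatory wiring per subtype? `atacohort` implements
that workflow end-to-end for analysts working with cohort ATAC-seq data
(the motivating setting is chronic lymphocytic leukaemia, with subtypes
defined by IGHV mutation status, but nothing is CLL-specific).

## What it computes

* **Consensus map** — the interval union of all per-sample peaks (BED
  0-based half-open; book-ended intervals merge), with per-region *support*
  (fraction of samples with an overlapping peak; classed constitutive /
  shared / rare) and a saturation curve with a 95% percentile band over
  randomised sample orderings.
* **Accessibility matrix** — fragments counted per region and sample, then
  quantile-normalised (reference = row means of the column-sorted matrix;
  ties get the mean reference value at their ranks). Per-region mean, SD,
  variance-to-mean ratio and squared coefficient of variation; gene-level
  promoter (closest region ≤ 1,000 bp from the TSS) and distal (mean of
  regions > 2,500 bp) summaries.
* **Accessibility corridor** — per-base cohort mean and 5/25/75/95th
  percentiles of depth-normalised coverage (reads per 10⁷ filtered reads),
  written as bedGraph tracks.
* **Differential variability** — per-region F test `F = s₁²/s₂²` between
  subtypes, two-sided p-values, Bonferroni correction over tested regions;
  significant = adjusted p < 0.05 and mean accessibility > 1, split by the
  higher-variance group.
* **Subtype classification** — random forest with patient-aware
  leave-one-out cross-validation (training sets never contain the test
  sample's patient), pooled out-of-fold ROC; AUC is the Mann–Whitney
  statistic with ties counted ½; shuffled-label nulls re-run the whole
  cross-validation per permutation. Signature regions are those with
  fold-averaged Gini importance > 10⁻⁴, directed by group means.
* **Intermediate subtypes** — average-linkage clustering on 1 − Pearson
  correlation over signature regions, plus PCA.
* **Regulatory networks** — footprint sites filtered by purity > 0.7 inside
  peaks, TFs kept with ≥ 500 qualifying sites; sites assigned to genes (gene
  body / 2,500 bp upstream window / nearest TSS); interaction score
  `S(t,g) = Σᵢ 2(Pᵢ − 0.5)·10^(−dᵢ/10⁶)`; edges where S > 1; differential
  connectivity = log2 ratio of edge-normalised node degrees between two
  networks.
* **Synthetic cohorts** — `cohort_spec()` / `generate_cohort()` draw a full
  cohort (peaks, fragments, counts, sample sheet, gene models, footprints)
  with planted subtype and variance structure and a complete ground-truth
  record, so every stage above is testable without patient data.

A file-based pipeline (`run_config()`, `run_pipeline()`; thin CLI at
`inst/scripts/run_pipeline.R`) chains the stages with a JSON run summary
carrying seeds, thresholds, timings and input checksums.

## Worked example

```r
library(atacohort)

cohort <- generate_cohort(cohort_spec(n_samples = 12, n_patients = 8, seed = 7,
  n_core_regions = 300, n_variable_regions = 60,
  n_sample_specific_regions_per_sample = 3,
  n_signature_regions = 30, n_diffvar_regions = 20, n_genes = 40))

consensus <- merge_peak_sets(cohort$peaks)
consensus
#> # A tibble: 396 × 4
#>    region_id           chrom  start    end
#>  1 chrS1_14901_15401   chrS1  14901  15401
#>  2 chrS1_45204_45704   chrS1  45204  45704
#>  ...

acc <- quantile_normalize(quantify_regions(consensus, cohort$fragments))
acc
#> <accessibility_matrix> 396 regions x 12 samples (raw + normalized layers)

labels <- ighv_labels(cohort$sample_sheet)
fit <- patient_aware_loocv(acc, labels,
                           cohort$sample_sheet[, c("sample_id", "patient_id")],
                           model_config = rf_config(num_trees = 200), seed = 7)
glance(fit)
#> # A tibble: 1 × 5
#>     auc sensitivity specificity n_samples n_regions
#> 1     1           1           1        12       396

glance(differential_variability(acc, labels))
#> # A tibble: 1 × 5
#>   n_regions n_tested n_skipped n_significant_mutated n_significant_unmutated
#> 1       396      396         0                     3                       4
```

The cross-validated AUC of 1 reflects the strong planted subtype effect
(1.5 log2 at 30 of 396 regions) in this small example: every held-out
sample is scored on the correct side. The differential-variability summary
says all 396 regions entered the F test and 7 were called significant
(3 more variable among mutated samples, 4 among unmutated); this example
cohort plants 20 diff-var regions, and the count recovered illustrates the
limited power of a Bonferroni-corrected variance test at 6-vs-6 samples.
`autoplot(fit)` draws the pooled ROC curve; `autoplot()` methods also exist
for saturation curves, corridor tracks and PCA projections, and `tidy()` /
`glance()` methods for the fitted objects.

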