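# Shared fixtures: all synthetic, generated in code.

# a small but structurally complete cohort spec; override any field
tiny_spec <- function(...) {
  defaults <- list(
    n_samples = 10, n_patients = 7,
    genome = c(chrA = 3e6, chrB = 3e6),
    n_core_regions = 80, n_variable_regions = 20,
    n_sample_specific_regions_per_sample = 2,
    n_signature_regions = 12, signature_log2_effect = 1.5,
    n_diffvar_regions = 12, diffvar_variance_ratio = 4,
    n_genes = 25,
    footprint_spec = list(
      n_tfs = 2, n_decoy_tfs = 1, sites_per_tf = c(70, 80),
      n_targets_per_tf = 2, n_proximal_sites = 12,
      n_decoy_genes_per_tf = 2, purity_shape = c(8, 2)
    ),
    seed = 11
  )
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

# cache the default tiny cohort across tests (generation is deterministic)
.cohort_cache <- new.env(parent = emptyenv())
tiny_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- generate_cohort(tiny_spec())
  }
  .cohort_cache$cohort
}

# simple interval tibble constructor
iv <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end), ...)
}

# per-base marking oracle for interval union on one chromosome:
# marks every covered base, then reads off maximal runs
union_oracle <- function(intervals, chrom_len = 10000) {
  out <- list()
  for (ch in unique(intervals$chrom)) {
    covered <- logical(chrom_len)
    sub <- intervals[intervals$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      covered[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    r <- rle(covered)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep] - 1L,
                                  end = stops[keep])
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# wrap a bare matrix as an accessibility_matrix (raw layer only)
new_acc_for_test <- function(m, totals = NULL) {
  new_accessibility_matrix(m, totals = totals)
}

# Mann-Whitney AUC oracle by explicit pair counting (ties count 1/2)
auc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
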