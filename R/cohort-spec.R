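#' Specify a synthetic ATAC-seq cohort
#'
#' Builds a validated specification for [generate_cohort()]. The defaults
#' describe a desk-scale cohort with the statistical structure of a large
#' patient ATAC-seq study: a shared core of accessible regions, a set of
#' regions present in only part of the cohort, a handful of regions private
#' to each sample, two disease subtypes defined by IGHV germline homology
#' with a planted accessibility difference at signature regions, regions with
#' a planted between-subtype variance ratio at equal means, and
#' transcription-factor footprint sites with purity scores supporting
#' regulatory-network inference.
#'
#' Counts are negative binomial in the mean/dispersion parameterisation
#' (`variance = mu + dispersion * mu^2`). At diff-var regions the dispersion
#' of the higher-variance group is scaled so the stated variance ratio is
#' achieved at an unchanged mean, so planted variance differences are not
#' confounded with mean shifts. Intermediate-subtype samples receive the
#' arithmetic midpoint of the two subtype means at signature regions and
#' IGHV homology values straddling the 98% threshold.
#'
#' @param n_samples Number of samples.
#' @param n_patients Number of patients (`<= n_samples`); when smaller, some
#'   patients contribute several samples.
#' @param genome Named vector of chromosome lengths in bp.
#' @param n_core_regions Regions accessible in every sample.
#' @param n_variable_regions Regions accessible in a random subset of samples.
#' @param n_sample_specific_regions_per_sample Regions private to each sample.
#' @param n_signature_regions Core regions with a planted subtype mean
#'   difference (half more accessible in the mutated subtype, half in the
#'   unmutated subtype).
#' @param signature_log2_effect Planted log2 mean difference between subtypes
#'   at signature regions.
#' @param n_diffvar_regions Core regions with a planted between-subtype
#'   variance ratio at equal means.
#' @param diffvar_variance_ratio Planted variance ratio (`> 1`).
#' @param baseline_mean Cohort-average expected count at an accessible
#'   region.
#' @param baseline_log_sd Log-scale standard deviation of per-region
#'   baselines: each region's accessible-state mean is drawn once from a
#'   mean-preserving lognormal around `baseline_mean`, emulating the wide
#'   spread of accessibility across real regulatory regions. This shared
#'   per-region profile is what makes sample-to-sample correlations
#'   meaningful; set to 0 for a flat baseline.
#' @param dispersion Negative-binomial dispersion (`> 0`).
#' @param background_mean Expected count at a region not called accessible in
#'   a sample.
#' @param variable_presence_prob Probability that a variable region is
#'   accessible in a given sample.
#' @param subtype_fraction_mutated Fraction of (non-intermediate) patients in
#'   the IGHV-mutated subtype.
#' @param intermediate_fraction Fraction of patients in the intermediate
#'   subtype.
#' @param n_genes Number of gene models to place.
#' @param gene_body_length Gene body length in bp.
#' @param region_length Width of every accessible region in bp.
#' @param fragment_length Width of simulated fragments in bp.
#' @param footprint_spec List describing the footprint component: `n_tfs`
#'   retained TFs, `n_decoy_tfs` TFs with too few sites to pass the filter,
#'   `sites_per_tf` (range of total sites per retained TF),
#'   `n_targets_per_tf` planted target genes per TF (each receiving
#'   `n_proximal_sites` high-purity sites at its promoter region),
#'   `n_decoy_genes_per_tf` decoy genes per TF (one weak qualifying site
#'   each), and `purity_shape` (Beta shape parameters; purity is
#'   `0.5 + 0.5 * Beta`, so scores live on `(0.5, 1]`).
#' @param seed Integer master seed; all sub-generators derive their streams
#'   from it.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [write_cohort()]
#' @export
cohort_spec <- function(n_samples = 40,
                        n_patients = 25,
                        genome = c(chrS1 = 6e6, chrS2 = 6e6),
                        n_core_regions = 1500,
                        n_variable_regions = 300,
                        n_sample_specific_regions_per_sample = 5,
                        n_signature_regions = 50,
                        signature_log2_effect = 1.5,
                        n_diffvar_regions = 50,
                        diffvar_variance_ratio = 4,
                        baseline_mean = 10,
                        baseline_log_sd = 0.5,
                        dispersion = 0.2,
                        background_mean = 0.5,
                        variable_presence_prob = 0.5,
                        subtype_fraction_mutated = 0.5,
                        intermediate_fraction = 0,
                        n_genes = 100,
                        gene_body_length = 4000,
                        region_length = 500,
                        fragment_length = 50,
                        footprint_spec = list(
                          n_tfs = 5, n_decoy_tfs = 2,
                          sites_per_tf = c(620, 700),
                          n_targets_per_tf = 3, n_proximal_sites = 25,
                          n_decoy_genes_per_tf = 3,
                          purity_shape = c(8, 2)
                        ),
                        seed = 1L) {
  genome <- check_genome(genome)
  spec <- list(
    n_samples = as.integer(n_samples), n_patients = as.integer(n_patients),
    genome = genome,
    n_core_regions = as.integer(n_core_regions),
    n_variable_regions = as.integer(n_variable_regions),
    n_sample_specific_regions_per_sample = as.integer(n_sample_specific_regions_per_sample),
    n_signature_regions = as.integer(n_signature_regions),
    signature_log2_effect = signature_log2_effect,
    n_diffvar_regions = as.integer(n_diffvar_regions),
    diffvar_variance_ratio = diffvar_variance_ratio,
    baseline_mean = baseline_mean, baseline_log_sd = baseline_log_sd,
    dispersion = dispersion,
    background_mean = background_mean,
    variable_presence_prob = variable_presence_prob,
    subtype_fraction_mutated = subtype_fraction_mutated,
    intermediate_fraction = intermediate_fraction,
    n_genes = as.integer(n_genes), gene_body_length = as.integer(gene_body_length),
    region_length = as.integer(region_length),
    fragment_length = as.integer(fragment_length),
    footprint_spec = footprint_spec,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_samples < 1) abort("n_samples must be >= 1")
  if (spec$n_patients > spec$n_samples) {
    abort("n_patients must not exceed n_samples")
  }
  if (spec$n_patients < 1) abort("n_patients must be >= 1")
  if (spec$n_signature_regions + spec$n_diffvar_regions > spec$n_core_regions) {
    abort("signature and diff-var regions must fit inside the core region set")
  }
  if (spec$diffvar_variance_ratio <= 1 && spec$n_diffvar_regions > 0) {
    abort("diffvar_variance_ratio must be > 1")
  }
  if (spec$baseline_mean <= 0) abort("baseline_mean must be > 0")
  if (spec$baseline_log_sd < 0) abort("baseline_log_sd must be >= 0")
  if (spec$dispersion <= 0) abort("dispersion must be > 0")
  if (spec$subtype_fraction_mutated <= 0 || spec$subtype_fraction_mutated >= 1) {
    abort("subtype_fraction_mutated must be in (0, 1)")
  }
  if (spec$intermediate_fraction < 0 || spec$intermediate_fraction >= 1) {
    abort("intermediate_fraction must be in [0, 1)")
  }
  if (spec$fragment_length > spec$region_length) {
    abort("fragment_length must not exceed region_length")
  }
  # region packing feasibility: every chromosome must fit its share of
  # regions with breathing room between neighbours
  m_total <- n_universe_regions(spec)
  alloc <- allocate_regions(spec$genome, m_total)
  spacing <- floor(spec$genome / pmax(alloc, 1L))
  if (any(alloc > 0 & spacing < 2 * spec$region_length)) {
    abort(sprintf(
      "cannot pack %d regions of %d bp into a genome of %.0f bp; enlarge the genome or reduce region counts",
      m_total, spec$region_length, sum(spec$genome)
    ))
  }
  invisible(spec)
}

n_universe_regions <- function(spec) {
  spec$n_core_regions + spec$n_variable_regions +
    spec$n_samples * spec$n_sample_specific_regions_per_sample
}

# proportional allocation of m regions over chromosomes (largest remainder)
allocate_regions <- function(genome, m) {
  share <- genome / sum(genome) * m
  base <- floor(share)
  rem <- m - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d samples / %d patients, genome %.1f Mb (%d chromosomes)\n",
              x$n_samples, x$n_patients, sum(x$genome) / 1e6, length(x$genome)))
  cat(sprintf("  regions: %d core (+%d signature, +%d diff-var), %d variable, %d per-sample\n",
              x$n_core_regions, x$n_signature_regions, x$n_diffvar_regions,
              x$n_variable_regions, x$n_sample_specific_regions_per_sample))
  cat(sprintf("  counts: NB(mean %.1f, dispersion %.2f); signature effect %.2f log2; variance ratio %.1f\n",
              x$baseline_mean, x$dispersion, x$signature_log2_effect, x$diffvar_variance_ratio))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
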