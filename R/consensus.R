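#' Build a cohort consensus region map
#'
#' Merges per-sample ATAC-seq peak calls into the interval union that serves
#' as the coordinate frame for all downstream quantification. Two input
#' intervals end up in the same consensus region iff they overlap or are
#' book-ended (touching end-to-start), matching the default behaviour of
#' standard interval-merge tools. Every input interval is contained in
#' exactly one consensus region.
#'
#' @param peaks A tibble of peak calls with columns `sample_id`, `chrom`,
#'   `start`, `end` (0-based, half-open), or a list of such tibbles
#'   (one per sample, `sample_id` optional within each).
#' @param exclude Optional tibble of intervals (e.g. a blacklist) removed
#'   from every peak set before merging: any peak overlapping an excluded
#'   interval by at least 1 bp is dropped.
#' @return A tibble of class `consensus_map` with columns `region_id`,
#'   `chrom`, `start`, `end`, sorted by position; the number of contributing
#'   samples is stored in the `n_samples` attribute.
#' @examples
#' peaks <- tibble::tibble(
#'   sample_id = c("a", "a", "b"),
#'   chrom = "chr1", start = c(0L, 200L, 50L), end = c(100L, 300L, 150L)
#' )
#' merge_peak_sets(peaks)
#' @export
merge_peak_sets <- function(peaks, exclude = NULL) {
  peaks <- normalise_peak_input(peaks)
  if (nrow(peaks) == 0) abort("cannot build a consensus map from empty peak sets")
  if (!is.null(exclude) && nrow(exclude) > 0) {
    check_intervals(exclude, "exclusion list")
    hit <- IRanges::overlapsAny(as_granges0(peaks), as_granges0(exclude))
    peaks <- peaks[!hit, ]
    if (nrow(peaks) == 0) abort("all peaks fall in excluded intervals")
  }
  merged <- GenomicRanges::reduce(as_granges0(peaks), min.gapwidth = 1L)
  out <- as_bed_tibble(merged) |>
    arrange(chrom, start) |>
    mutate(region_id = region_id_string(chrom, start, end), .before = 1)
  structure(out, class = c("consensus_map", class(tibble())),
            n_samples = length(unique(peaks$sample_id)))
}

# accept either a long tibble with sample_id or a (named) list of per-sample
# tibbles; always returns the long form with a sample_id column
normalise_peak_input <- function(peaks) {
  if (is.data.frame(peaks)) {
    if (!"sample_id" %in% names(peaks)) {
      peaks <- mutate(peaks, sample_id = "sample_1", .before = 1)
    }
  } else if (is.list(peaks)) {
    if (length(peaks) == 0) abort("cannot build a consensus map from an empty list of peak sets")
    ids <- names(peaks) %||% paste0("sample_", seq_along(peaks))
    if (is.null(names(peaks))) names(peaks) <- ids
    peaks <- map_dfr(ids, function(id) {
      mutate(peaks[[id]], sample_id = id, .before = 1)
    })
    # keep samples whose table is empty: they still deserve a column/curve
    attr_ids <- ids
    peaks <- structure(peaks, all_sample_ids = attr_ids)
    check_intervals(peaks, "peak table")
    return(peaks)
  } else {
    abort("peaks must be a data frame or a list of data frames")
  }
  check_intervals(peaks, "peak table")
  peaks
}

#' Saturation analysis of the consensus map
#'
#' Adds samples in random order and records how many distinct merged regions
#' the first k samples produce, repeated over many random orderings. The
#' curve's mean and a 95% percentile band (2.5th/97.5th percentiles across
#' orderings) summarise how quickly the region universe saturates as the
#' cohort grows.
#'
#' @inheritParams merge_peak_sets
#' @param n_iterations Number of random sample orderings.
#' @param seed Integer seed for the orderings.
#' @return A tibble of class `saturation_result` with columns `n_samples`,
#'   `mean`, `ci_low`, `ci_high`; the iteration count is stored as an
#'   attribute.
#' @export
saturation_curve <- function(peaks, n_iterations = 1000, seed = 1L) {
  peaks <- normalise_peak_input(peaks)
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  by_sample <- split(peaks, peaks$sample_id)
  granges <- map(by_sample, as_granges0)
  n <- length(granges)
  curves <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_iterations), function(it) {
      ord <- sample.int(n)
      acc <- NULL
      out <- integer(n)
      for (k in seq_len(n)) {
        acc <- if (is.null(acc)) {
          GenomicRanges::reduce(granges[[ord[k]]], min.gapwidth = 1L)
        } else {
          GenomicRanges::reduce(c(acc, granges[[ord[k]]]), min.gapwidth = 1L)
        }
        out[k] <- length(acc)
      }
      out
    }, integer(n))
  })
  curves <- matrix(curves, nrow = n)
  out <- tibble(
    n_samples = seq_len(n),
    mean = rowMeans(curves),
    ci_low = apply(curves, 1, quantile, probs = 0.025, names = FALSE),
    ci_high = apply(curves, 1, quantile, probs = 0.975, names = FALSE)
  )
  structure(out, class = c("saturation_result", class(tibble())),
            n_iterations = n_iterations, seed = as.integer(seed))
}

#' Per-region sample support
#'
#' Support of a consensus region is the fraction of samples with at least
#' one called peak overlapping it by 1 bp or more. Regions are additionally
#' classified as `constitutive` (support > 0.95), `rare` (support <= 0.05 or
#' a single supporting sample) or `shared` (everything between); the
#' boundary convention is recorded in the `support_boundaries` attribute.
#'
#' @param consensus A `consensus_map` from [merge_peak_sets()].
#' @param peaks The peak sets used to build the consensus (long tibble or
#'   list form).
#' @param constitutive Support above this fraction is called constitutive.
#' @param rare Support at or below this fraction is called rare.
#' @return The consensus tibble with added columns `n_supporting`, `support`
#'   and `support_class`.
#' @export
region_support <- function(consensus, peaks, constitutive = 0.95, rare = 0.05) {
  check_intervals(consensus, "consensus map", c("region_id", "chrom", "start", "end"))
  peaks <- normalise_peak_input(peaks)
  n_samples <- length(unique(peaks$sample_id))
  expected <- attr(consensus, "n_samples")
  if (!is.null(expected) && expected != n_samples) {
    abort(sprintf(
      "peak sets cover %d samples but the consensus map was built from %d",
      n_samples, expected
    ))
  }
  cons_gr <- as_granges0(consensus)
  hits <- GenomicRanges::findOverlaps(cons_gr, as_granges0(peaks))
  supp_n <- tibble(
    region = S4Vectors::queryHits(hits),
    sample_id = peaks$sample_id[S4Vectors::subjectHits(hits)]
  ) |>
    distinct() |>
    count(.data$region)
  n_supporting <- integer(nrow(consensus))
  n_supporting[supp_n$region] <- supp_n$n
  out <- consensus |>
    mutate(
      n_supporting = n_supporting,
      support = n_supporting / n_samples,
      support_class = case_when(
        support > constitutive ~ "constitutive",
        n_supporting == 1 | support <= rare ~ "rare",
        TRUE ~ "shared"
      )
    )
  attr(out, "n_samples") <- n_samples
  attr(out, "support_boundaries") <- c(constitutive = constitutive, rare = rare)
  out
}

#' Genomic co-localization of regions with feature classes
#'
#' For each feature class, reports the fraction of regions overlapping the
#' class by at least 1 bp (`frequency`) and the base-pair enrichment over a
#' uniform genomic background (`fold_change`): the fraction of region bases
#' inside the class divided by the class's fraction of the genome.
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`).
#' @param features Interval tibble with an additional `class` column.
#' @param genome Named vector of chromosome lengths (or tibble with columns
#'   `chrom`, `length`).
#' @return A tibble with one row per feature class: `class`, `frequency`,
#'   `fold_change`.
#' @export
co_localization <- function(regions, features, genome) {
  check_intervals(regions, "region table")
  check_intervals(features, "feature table", c("chrom", "start", "end", "class"))
  genome <- check_genome(genome)
  genome_bp <- sum(genome)
  if (genome_bp <= 0) abort("genome has zero total length")
  region_gr <- as_granges0(regions)
  total_region_bp <- sum(GenomicRanges::width(region_gr))
  if (total_region_bp == 0) abort("regions have zero total length")

  map_dfr(split(features, features$class), function(f) {
    f_gr <- GenomicRanges::reduce(as_granges0(f))
    class_bp <- sum(GenomicRanges::width(f_gr))
    if (class_bp == 0) abort(sprintf("feature class '%s' has zero total length", f$class[1]))
    freq <- mean(IRanges::overlapsAny(region_gr, f_gr))
    inside_bp <- sum(GenomicRanges::width(GenomicRanges::intersect(
      GenomicRanges::reduce(region_gr), f_gr
    )))
    tibble(
      class = f$class[1],
      frequency = freq,
      fold_change = (inside_bp / total_region_bp) / (class_bp / genome_bp)
    )
  })
}

#' Annotate regions with their nearest transcription start site
#'
#' Distance is measured from the region midpoint to the TSS and is 0 when
#' the TSS falls inside the region. Ties are broken towards the
#' lexicographically smallest gene ID. Regions on chromosomes without any
#' gene are annotated with `NA`.
#'
#' @param regions Interval tibble; a `region_id` column is added if absent.
#' @param genes Gene model tibble with columns `gene_id`, `chrom`, `strand`,
#'   `tss` (see [read_gene_models()]).
#' @return A tibble with columns `region_id`, `gene_id`, `distance`
#'   (non-negative midpoint-to-TSS distance, bp; 0 if the TSS lies inside
#'   the region) and `signed_distance` (positive when the region midpoint
#'   lies downstream of the TSS in the gene's orientation).
#' @export
annotate_nearest_tss <- function(regions, genes) {
  check_intervals(regions, "region table")
  if (nrow(genes) == 0) abort("gene table is empty")
  if (!all(c("gene_id", "chrom", "strand", "tss") %in% names(genes))) {
    abort("genes must have columns gene_id, chrom, strand, tss")
  }
  regions <- ensure_region_ids(regions)
  mid <- interval_midpoint(regions$start, regions$end)

  genes_sorted <- genes |> arrange(chrom, tss, gene_id)
  by_chrom <- split(genes_sorted, genes_sorted$chrom)

  res <- map_dfr(seq_len(nrow(regions)), function(i) {
    g <- by_chrom[[regions$chrom[i]]]
    if (is.null(g)) {
      return(tibble(region_id = regions$region_id[i], gene_id = NA_character_,
                    distance = NA_real_, signed_distance = NA_real_))
    }
    d <- abs(g$tss - mid[i])
    # TSS inside the half-open region counts as distance zero
    inside <- g$tss >= regions$start[i] & g$tss < regions$end[i]
    d[inside] <- 0
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
    sgn <- if (g$strand[best] == "+") mid[i] - g$tss[best] else g$tss[best] - mid[i]
    tibble(region_id = regions$region_id[i], gene_id = g$gene_id[best],
           distance = min(d), signed_distance = if (min(d) == 0) 0 else sgn)
  })
  res
}

ensure_region_ids <- function(regions) {
  if (!"region_id" %in% names(regions)) {
    regions <- mutate(regions, region_id = region_id_string(chrom, start, end), .before = 1)
  }
  regions
}
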