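#' Per-base fragment coverage over requested loci
#'
#' Computes, for every base of the requested loci, how many fragments of
#' each sample cover it. Corridor tracks are computed per locus rather than
#' genome-wide to stay desk-scale; loci are typically consensus regions of
#' interest, padded as desired.
#'
#' @param fragments Fragment tibble (`sample_id`, `chrom`, `start`, `end`)
#'   or named list of per-sample tibbles.
#' @param loci Interval tibble of loci to cover (0-based, half-open).
#' @return A long tibble with columns `sample_id`, `chrom`, `pos` (0-based
#'   base position) and `coverage`.
#' @export
fragment_coverage <- function(fragments, loci) {
  fragments <- normalise_peak_input(fragments)
  check_intervals(loci, "locus table")
  samples <- sort(unique(fragments$sample_id))
  loci_gr <- as_granges0(loci)
  map_dfr(samples, function(s) {
    fr <- fragments[fragments$sample_id == s, ]
    cov <- GenomicRanges::coverage(as_granges0(fr))
    map_dfr(seq_len(nrow(loci)), function(i) {
      pos <- loci$start[i]:(loci$end[i] - 1L)
      chrom <- loci$chrom[i]
      vals <- if (chrom %in% names(cov)) {
        rl <- cov[[chrom]]
        idx1 <- pos + 1L  # 1-based into the coverage vector
        ok <- idx1 <= length(rl)
        v <- numeric(length(pos))
        if (any(ok)) v[ok] <- as.numeric(rl[idx1[ok]])
        v
      } else {
        numeric(length(pos))
      }
      tibble(sample_id = s, chrom = chrom, pos = pos, coverage = vals)
    })
  })
}

#' Normalise a coverage track by sequencing depth
#'
#' Scales per-base coverage to reads per ten million filtered reads:
#' `value * 1e7 / total_filtered_reads`, making tracks comparable across
#' samples of different depth.
#'
#' @param coverage Numeric vector of per-base coverage, or a tibble with a
#'   `coverage` column.
#' @param total_filtered_reads Total filtered read (fragment) count of the
#'   sample; must be positive.
#' @param scale Scaling constant (default ten million).
#' @return The normalised vector, or the tibble with a `normalized` column
#'   added.
#' @export
normalize_coverage <- function(coverage, total_filtered_reads, scale = 1e7) {
  if (total_filtered_reads <= 0) abort("total_filtered_reads must be positive")
  if (is.data.frame(coverage)) {
    if (!"coverage" %in% names(coverage)) abort("coverage tibble needs a 'coverage' column")
    return(mutate(coverage, normalized = .data$coverage / total_filtered_reads * scale))
  }
  coverage / total_filtered_reads * scale
}

#' Cohort accessibility corridor
#'
#' Summarises normalised per-base coverage across the cohort into the mean
#' and the 5th, 25th, 75th and 95th percentiles per base — the
#' "chromatin accessibility corridor" view of cohort heterogeneity.
#' Percentiles use linear interpolation between order statistics
#' (recorded in the `percentile_method` attribute).
#'
#' @param coverage Long tibble from [fragment_coverage()] with a value
#'   column named by `value_col`; all samples must cover identical loci.
#' @param value_col Column to summarise (e.g. `"normalized"` after
#'   [normalize_coverage()], or `"coverage"`).
#' @return A tibble of class `corridor_track` with columns `chrom`, `pos`,
#'   `mean`, `p5`, `p25`, `p75`, `p95`.
#' @export
corridor_tracks <- function(coverage, value_col = "coverage") {
  need <- c("sample_id", "chrom", "pos", value_col)
  if (!all(need %in% names(coverage))) {
    abort(sprintf("coverage must have columns %s", paste(need, collapse = ", ")))
  }
  n_samples <- length(unique(coverage$sample_id))
  if (n_samples < 2) abort("corridor tracks need at least 2 samples")
  per_pos <- coverage |> count(chrom, pos)
  if (any(per_pos$n != n_samples)) {
    abort("inconsistent loci: every position must be covered by every sample")
  }
  out <- coverage |>
    group_by(chrom, pos) |>
    summarise(
      mean = mean(.data[[value_col]]),
      p5 = quantile(.data[[value_col]], 0.05, names = FALSE, type = 7),
      p25 = quantile(.data[[value_col]], 0.25, names = FALSE, type = 7),
      p75 = quantile(.data[[value_col]], 0.75, names = FALSE, type = 7),
      p95 = quantile(.data[[value_col]], 0.95, names = FALSE, type = 7),
      .groups = "drop"
    ) |>
    arrange(chrom, pos)
  structure(out, class = c("corridor_track", class(tibble())),
            percentile_method = "linear interpolation between order statistics (R type 7)")
}

#' Write corridor statistics as bedGraph tracks
#'
#' One bedGraph file per statistic (`mean`, `p5`, `p25`, `p75`, `p95`),
#' named `<prefix>.<stat>.bedGraph`.
#'
#' @param corridor A `corridor_track`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_corridor_bedgraphs <- function(corridor, prefix) {
  stats <- c("mean", "p5", "p25", "p75", "p95")
  paths <- vapply(stats, function(s) {
    p <- sprintf("%s.%s.bedGraph", prefix, s)
    write_bedgraph(corridor, p, value_col = s)
    p
  }, character(1))
  invisible(paths)
}
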