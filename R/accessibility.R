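#' @title Region-by-sample accessibility matrices
#' @description Internal constructor for the `accessibility_matrix` class:
#'   a regions x samples count matrix (`raw`), an optional
#'   quantile-normalised layer (`normalized`), per-sample total filtered
#'   read counts (`totals`) and a QC record.
#' @keywords internal
new_accessibility_matrix <- function(raw, totals = NULL, normalized = NULL, qc = list()) {
  stopifnot(is.matrix(raw), !is.null(rownames(raw)), !is.null(colnames(raw)))
  if (is.null(totals)) totals <- colSums(raw)
  structure(list(raw = raw, normalized = normalized,
                 totals = totals[colnames(raw)], qc = qc),
            class = "accessibility_matrix")
}

#' @export
print.accessibility_matrix <- function(x, ...) {
  cat(sprintf("<accessibility_matrix> %d regions x %d samples (%s)\n",
              nrow(x$raw), ncol(x$raw),
              if (is.null(x$normalized)) "raw layer only" else "raw + normalized layers"))
  invisible(x)
}

#' @export
dim.accessibility_matrix <- function(x) dim(x$raw)

# pick a layer, defaulting to normalized when present
acc_layer <- function(acc, layer = c("normalized", "raw")) {
  layer <- match.arg(layer)
  if (layer == "normalized") {
    if (is.null(acc$normalized)) abort("normalized layer not present; run quantile_normalize() first")
    acc$normalized
  } else {
    acc$raw
  }
}

#' @describeIn quantify_regions Long-format view of an accessibility matrix.
#' @param x An `accessibility_matrix`.
#' @param ... Unused.
#' @export
tidy.accessibility_matrix <- function(x, ...) {
  out <- as_tibble(x$raw, rownames = "region_id") |>
    tidyr::pivot_longer(-region_id, names_to = "sample_id", values_to = "raw")
  if (!is.null(x$normalized)) {
    norm_long <- as_tibble(x$normalized, rownames = "region_id") |>
      tidyr::pivot_longer(-region_id, names_to = "sample_id", values_to = "normalized")
    out <- left_join(out, norm_long, by = c("region_id", "sample_id"))
  }
  out
}

#' Quantify accessibility over consensus regions
#'
#' Entry (r, s) of the raw layer is the number of sample-s fragments
#' overlapping region r by at least 1 bp (half-open interval overlap). A
#' fragment is counted once per region it touches; a fragment spanning
#' several regions contributes to each. Fragments on chromosomes absent
#' from the consensus map are skipped with a warning and recorded in the QC
#' report.
#'
#' @param consensus A `consensus_map` (or any interval tibble with a
#'   `region_id` column).
#' @param fragments Fragment tibble with columns `sample_id`, `chrom`,
#'   `start`, `end`, or a named list of per-sample tibbles.
#' @return An `accessibility_matrix` with the raw layer filled in and
#'   per-sample fragment totals.
#' @export
quantify_regions <- function(consensus, fragments) {
  check_intervals(consensus, "consensus map", c("region_id", "chrom", "start", "end"))
  if (nrow(consensus) == 0) abort("consensus map is empty")
  fragments <- normalise_peak_input(fragments)
  known <- unique(consensus$chrom)
  off <- !(fragments$chrom %in% known)
  n_skipped <- sum(off)
  if (n_skipped > 0) {
    warn(sprintf("%d fragment(s) on chromosomes absent from the consensus map were skipped", n_skipped))
  }
  totals <- fragments |> count(sample_id, name = "total")
  kept <- fragments[!off, ]
  cons_gr <- as_granges0(consensus)
  samples <- attr(fragments, "all_sample_ids") %||% sort(unique(fragments$sample_id))
  raw <- matrix(0L, nrow(consensus), length(samples),
                dimnames = list(consensus$region_id, samples))
  for (s in samples) {
    fr <- kept[kept$sample_id == s, ]
    if (nrow(fr) == 0) next
    raw[, s] <- GenomicRanges::countOverlaps(cons_gr, as_granges0(fr))
  }
  tot <- setNames(rep(0L, length(samples)), samples)
  tot[totals$sample_id] <- totals$total
  new_accessibility_matrix(raw, totals = tot,
                           qc = list(n_fragments_skipped = n_skipped))
}

#' Quantile-normalise an accessibility matrix
#'
#' Classical quantile normalisation: the reference distribution is the
#' row-wise mean of the column-sorted raw matrix, and each column's values
#' are replaced by the reference values at their ranks. Ties within a
#' column receive the mean of the reference values at the tied rank
#' positions, so after normalisation every tie-free column carries the
#' identical multiset of values. The operation is idempotent.
#'
#' @param acc An `accessibility_matrix` (raw layer used), or a bare numeric
#'   matrix.
#' @return The input with the `normalized` layer filled in (or a bare
#'   matrix if a matrix was supplied).
#' @export
quantile_normalize <- function(acc) {
  if (is.matrix(acc)) {
    return(quantile_normalize_matrix(acc))
  }
  if (!inherits(acc, "accessibility_matrix")) {
    abort("acc must be an accessibility_matrix or a numeric matrix")
  }
  acc$normalized <- quantile_normalize_matrix(acc$raw)
  acc
}

quantile_normalize_matrix <- function(x) {
  if (ncol(x) < 2) abort("quantile normalization needs at least 2 samples")
  if (any(x < 0)) abort("quantile normalization expects non-negative values")
  reference <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    # fractional ranks from ties pick up the mean of the reference values
    # at the tied positions (linear interpolation on the sorted reference)
    approx(seq_along(reference), reference, xout = rk)$y
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Cohort variability statistics per region
#'
#' For each region, the across-sample mean, standard deviation (n-1
#' denominator), variance-to-mean ratio and squared coefficient of
#' variation. Regions with zero mean have undefined VMR/CV2 and are
#' flagged.
#'
#' @param acc An `accessibility_matrix`.
#' @param layer Which layer to summarise (default the normalised one).
#' @return A tibble with columns `region_id`, `mean`, `sd`, `vmr`, `cv2`,
#'   `flag`.
#' @export
variability_metrics <- function(acc, layer = c("normalized", "raw")) {
  x <- acc_layer(acc, match.arg(layer))
  m <- unname(rowMeans(x))
  s <- unname(apply(x, 1, sd))
  v <- s^2
  vmr <- ifelse(m > 0, v / m, NA_real_)
  cv2 <- ifelse(m > 0, (s / m)^2, NA_real_)
  vmr[s == 0 & m > 0] <- 0
  cv2[s == 0 & m > 0] <- 0
  tibble(
    region_id = rownames(x), mean = m, sd = s, vmr = vmr, cv2 = cv2,
    flag = ifelse(m == 0, "zero_mean", NA_character_)
  )
}

#' Summarise accessibility to gene level
#'
#' The promoter value of a gene in a sample is the accessibility of the
#' closest region whose midpoint lies within 1,000 bp of the gene's TSS;
#' the distal value is the mean over all of the gene's regions farther than
#' 2,500 bp from the TSS. Regions between the two cutoffs belong to
#' neither summary. Genes without qualifying regions get `NA`.
#'
#' @param acc An `accessibility_matrix`.
#' @param tss_annotation Output of [annotate_nearest_tss()] for the matrix's
#'   regions.
#' @param promoter_bp Maximum TSS distance for the promoter summary.
#' @param distal_bp Minimum TSS distance for the distal summary.
#' @param layer Which layer to summarise.
#' @return A long tibble with columns `gene_id`, `sample_id`, `promoter`,
#'   `distal`.
#' @export
summarize_by_gene <- function(acc, tss_annotation, promoter_bp = 1000,
                              distal_bp = 2500, layer = c("normalized", "raw")) {
  x <- acc_layer(acc, match.arg(layer))
  ann <- tss_annotation |>
    filter(!is.na(gene_id), region_id %in% rownames(x))
  prom <- ann |>
    filter(distance <= promoter_bp) |>
    group_by(gene_id) |>
    slice_min(distance, n = 1, with_ties = FALSE) |>
    ungroup()
  dist <- ann |> filter(distance > distal_bp)

  genes <- sort(unique(ann$gene_id))
  samples <- colnames(x)
  prom_mat <- matrix(NA_real_, length(genes), length(samples),
                     dimnames = list(genes, samples))
  if (nrow(prom) > 0) {
    prom_mat[prom$gene_id, ] <- x[prom$region_id, , drop = FALSE]
  }
  dist_mat <- matrix(NA_real_, length(genes), length(samples),
                     dimnames = list(genes, samples))
  if (nrow(dist) > 0) {
    sums <- rowsum(x[dist$region_id, , drop = FALSE], group = dist$gene_id)
    n_per <- as.vector(table(dist$gene_id)[rownames(sums)])
    dist_mat[rownames(sums), ] <- sums / n_per
  }
  tibble(
    gene_id = rep(genes, times = length(samples)),
    sample_id = rep(samples, each = length(genes)),
    promoter = as.vector(prom_mat),
    distal = as.vector(dist_mat)
  )
}
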