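#' Correlation-based hierarchical clustering of samples
#'
#' Clusters samples on their accessibility profiles over a region set
#' (typically the signature regions): the distance between two samples is
#' one minus the Pearson correlation of their profiles, linkage is
#' average, and the dendrogram is cut into `k` clusters. Used to look for
#' intermediate disease subtypes between the two labelled ones.
#'
#' @param acc An `accessibility_matrix`.
#' @param regions Region IDs to cluster on (e.g. `region_id` column of a
#'   signature), or `NULL` for all regions.
#' @param k Number of clusters to cut.
#' @param layer Matrix layer.
#' @return A tibble of class `cluster_assignment` with columns
#'   `sample_id`, `cluster`; the `hclust` object and dendrogram order are
#'   stored in attributes.
#' @export
cluster_samples <- function(acc, regions = NULL, k = 4, layer = c("normalized", "raw")) {
  x <- acc_layer(acc, match.arg(layer))
  if (!is.null(regions)) {
    missing_regions <- setdiff(regions, rownames(x))
    if (length(missing_regions) > 0) {
      abort(sprintf("%d requested region(s) absent from the matrix", length(missing_regions)))
    }
    x <- x[regions, , drop = FALSE]
  }
  if (nrow(x) < 2) abort("clustering needs at least 2 regions")
  if (ncol(x) < k) abort(sprintf("cannot cut %d samples into %d clusters", ncol(x), k))
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant profile (undefined correlation) for sample %s",
                  colnames(x)[which(sds == 0)[1]]))
  }
  d <- as.dist(1 - cor(x))
  hc <- hclust(d, method = "average")
  assignment <- cutree(hc, k = k)
  out <- tibble(sample_id = colnames(x), cluster = unname(assignment))
  structure(out, class = c("cluster_assignment", class(tibble())),
            hclust = hc, dendrogram_order = colnames(x)[hc$order], k = k)
}

#' Principal component analysis of sample accessibility profiles
#'
#' Centred singular-value decomposition of the samples-by-regions matrix.
#'
#' @param acc An `accessibility_matrix`.
#' @param n_components Number of components to return.
#' @param regions Optional region IDs to restrict to.
#' @param layer Matrix layer.
#' @return A tibble of class `pca_projection` with `sample_id` and one
#'   column per component (`PC1`, `PC2`, ...); explained-variance fractions
#'   are stored in the `explained_variance` attribute.
#' @export
pca_projection <- function(acc, n_components = 2, regions = NULL,
                           layer = c("normalized", "raw")) {
  x <- acc_layer(acc, match.arg(layer))
  if (!is.null(regions)) x <- x[regions, , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) abort("PCA needs at least 2 regions and 2 samples")
  xs <- t(x)  # samples x regions
  if (all(apply(xs, 2, sd) == 0)) abort("matrix is constant: PCA is degenerate")
  fit <- prcomp(xs, center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(fit$x))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  out <- as_tibble(fit$x[, seq_len(n_components), drop = FALSE]) |>
    mutate(sample_id = rownames(xs), .before = 1)
  structure(out, class = c("pca_projection", class(tibble())),
            explained_variance = ev[seq_len(n_components)])
}
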