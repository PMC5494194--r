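#' Assign IGHV mutation-status labels
#'
#' A sample is called `unmutated` when its IGHV germline homology exceeds
#' the threshold (strictly greater than 98% by default), `mutated` at or
#' below it, and `unknown` when the homology is missing; unknown samples
#' are excluded from downstream group analyses.
#'
#' @param sheet Sample sheet tibble with columns `sample_id` and
#'   `ighv_homology` (percent, in `[80, 100]` where present).
#' @param threshold Homology threshold in percent.
#' @return A tibble with columns `sample_id`, `ighv_label` (factor with
#'   levels mutated, unmutated, unknown).
#' @export
ighv_labels <- function(sheet, threshold = 98) {
  if (!all(c("sample_id", "ighv_homology") %in% names(sheet))) {
    abort("sheet must have columns sample_id and ighv_homology")
  }
  h <- sheet$ighv_homology
  if (any(!is.na(h) & (h < 0 | h > 100))) {
    abort("ighv_homology values must lie in [0, 100]")
  }
  tibble(
    sample_id = sheet$sample_id,
    ighv_label = factor(
      case_when(is.na(h) ~ "unknown", h > threshold ~ "unmutated", TRUE ~ "mutated"),
      levels = c("mutated", "unmutated", "unknown")
    )
  )
}

# resolve a label argument (tibble from ighv_labels() or named vector)
# against a sample ordering; returns a factor, possibly with "unknown"
resolve_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "ighv_label") %in% names(labels))) {
      abort("labels tibble must have columns sample_id and ighv_label")
    }
    v <- setNames(as.character(labels$ighv_label), labels$sample_id)[sample_ids]
  } else {
    v <- as.character(labels)
    if (!is.null(names(labels))) v <- setNames(v, names(labels))[sample_ids]
    if (length(v) != length(sample_ids)) {
      abort("labels must cover every sample in the matrix")
    }
  }
  if (any(is.na(v))) v[is.na(v)] <- "unknown"
  factor(v, levels = c("mutated", "unmutated", "unknown"))
}

#' Differential chromatin variability between subtypes
#'
#' Per region, an F test of equal variances between the two labelled groups:
#' `F = s1^2 / s2^2` (sample variances, n-1 denominator; group 1 =
#' mutated), with the two-sided p-value `2 * min(P(F >= f), P(F <= f))`
#' capped at 1, from the F distribution with `(n1 - 1, n2 - 1)` degrees of
#' freedom. Bonferroni correction uses the number of regions actually
#' tested. A region is significant when its Bonferroni-adjusted p-value is
#' below `alpha` and its overall mean exceeds `mean_cutoff`; significant
#' regions are split by which group has the larger variance. Regions with
#' zero variance in both groups are skipped; zero variance in exactly one
#' group gives the limiting p-value 0 and a flag.
#'
#' @param acc An `accessibility_matrix`.
#' @param labels Labels from [ighv_labels()] (tibble or named vector);
#'   `unknown` samples are excluded.
#' @param alpha Significance level on the Bonferroni-adjusted p-value.
#' @param mean_cutoff Minimum overall mean accessibility for significance.
#' @param layer Matrix layer to test.
#' @return A tibble of class `diffvar_result`, one row per region:
#'   `region_id`, `mean`, `var_mutated`, `var_unmutated`, `f_stat`,
#'   `p_value`, `p_bonferroni`, `higher_group`, `significant`, `flag`.
#'   Group sizes and the Bonferroni denominator are stored as attributes.
#' @export
differential_variability <- function(acc, labels, alpha = 0.05, mean_cutoff = 1,
                                     layer = c("normalized", "raw")) {
  x <- acc_layer(acc, match.arg(layer))
  lab <- resolve_labels(labels, colnames(x))
  g1 <- which(lab == "mutated")
  g2 <- which(lab == "unmutated")
  if (length(g1) < 2 || length(g2) < 2) {
    abort("both groups need at least 2 labelled samples")
  }
  v1 <- unname(apply(x[, g1, drop = FALSE], 1, var))
  v2 <- unname(apply(x[, g2, drop = FALSE], 1, var))
  m <- unname(rowMeans(x[, c(g1, g2), drop = FALSE]))
  df1 <- length(g1) - 1
  df2 <- length(g2) - 1

  both_zero <- v1 == 0 & v2 == 0
  one_zero <- xor(v1 == 0, v2 == 0)
  f <- v1 / v2
  p <- pmin(2 * pmin(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE)), 1)
  p[both_zero] <- NA_real_
  p[one_zero] <- 0  # limiting value of the two-sided tail

  n_tested <- sum(!both_zero)
  p_bonf <- pmin(p * n_tested, 1)
  higher <- ifelse(v1 > v2, "mutated", ifelse(v2 > v1, "unmutated", NA_character_))
  sig <- !is.na(p_bonf) & p_bonf < alpha & m > mean_cutoff

  out <- tibble(
    region_id = rownames(x),
    mean = m, var_mutated = v1, var_unmutated = v2,
    f_stat = ifelse(both_zero, NA_real_, f),
    p_value = p, p_bonferroni = p_bonf,
    higher_group = higher,
    significant = sig,
    flag = case_when(
      both_zero ~ "skipped_zero_variance",
      one_zero ~ "one_group_zero_variance",
      TRUE ~ NA_character_
    )
  )
  structure(out, class = c("diffvar_result", class(tibble())),
            n_tested = n_tested, df = c(df1, df2),
            group_sizes = c(mutated = length(g1), unmutated = length(g2)),
            alpha = alpha, mean_cutoff = mean_cutoff)
}

#' @describeIn differential_variability One-row summary: regions tested,
#'   skipped and significant per group.
#' @param x A `diffvar_result`.
#' @param ... Unused.
#' @export
glance.diffvar_result <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    n_tested = attr(x, "n_tested"),
    n_skipped = sum(x$flag == "skipped_zero_variance", na.rm = TRUE),
    n_significant_mutated = sum(x$significant & x$higher_group == "mutated", na.rm = TRUE),
    n_significant_unmutated = sum(x$significant & x$higher_group == "unmutated", na.rm = TRUE)
  )
}
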