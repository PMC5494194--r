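#' Random-forest configuration for subtype classification
#'
#' Configuration of the impurity-based tree ensemble used by
#' [patient_aware_loocv()]. Defaults: 500 trees, `sqrt(p)` candidate
#' features per split, terminal nodes of at least 10 observations (the
#' usual probability-forest default, giving calibrated class
#' probabilities), a class-balanced bootstrap per tree (each tree draws
#' the same number of observations from both classes), and per-fold score
#' calibration.
#'
#' The last two settings exist because pooled leave-one-out ROC curves
#' compare scores produced by different training sets: each held-out
#' sample depresses its own class's training prevalence, which biases the
#' pooled curve pessimistic (null AUC well below 0.5 at small n). The
#' balanced bootstrap removes the prevalence signal from every tree, and
#' calibration re-centres each fold's score by the training set's
#' out-of-bag mean score, making scores comparable across folds.
#'
#' @param num_trees Number of trees.
#' @param mtry Candidate features per split (`NULL` for `sqrt(p)`).
#' @param min_node_size Minimal terminal node size; `NULL` (default) uses
#'   `min(10, ceiling(n_train / 4))` per fold — the probability-forest
#'   default of 10, scaled down so trees can still split in very small
#'   training sets.
#' @param max_depth Maximal tree depth (`NULL` for unlimited).
#' @param balanced_bootstrap Draw class-balanced per-tree bootstrap samples.
#' @param sample_fraction Bootstrap fraction (of the minority class size
#'   when balanced).
#' @param calibrate_scores Re-centre each fold's out-of-fold score by the
#'   training set's out-of-bag mean score (clamped to `[0, 1]`).
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(num_trees = 500, mtry = NULL, min_node_size = NULL,
                      max_depth = NULL, balanced_bootstrap = TRUE,
                      sample_fraction = 0.632, calibrate_scores = TRUE) {
  structure(list(num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size, max_depth = max_depth,
                 balanced_bootstrap = balanced_bootstrap,
                 sample_fraction = sample_fraction,
                 calibrate_scores = calibrate_scores),
            class = "rf_config")
}

# fit one fold's forest and return the test sample's P(mutated) plus
# normalized impurity importances
fit_fold <- function(x_train, y_train, x_test, config, seed) {
  node_size <- config$min_node_size %||%
    min(10, ceiling(nrow(x_train) / 4))
  args <- list(
    x = x_train, y = y_train,
    num.trees = config$num_trees,
    min.node.size = node_size,
    probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1
  )
  if (!is.null(config$mtry)) args$mtry <- config$mtry
  if (!is.null(config$max_depth)) args$max.depth <- config$max_depth
  if (isTRUE(config$balanced_bootstrap)) {
    n_min <- min(table(y_train))
    args$replace <- TRUE
    # class-wise fraction of the total training size; at least one draw per class
    args$sample.fraction <- rep(max(config$sample_fraction * n_min, 1) / length(y_train), 2)
  }
  fit <- do.call(ranger::ranger, args)
  pred <- stats::predict(fit, data.frame(x_test, check.names = FALSE))$predictions
  score <- unname(pred[, "mutated"])
  if (isTRUE(config$calibrate_scores)) {
    # re-centre by the fold's out-of-bag mean score so that scores are
    # comparable across folds with different training compositions
    oob <- fit$predictions[, "mutated"]
    score <- min(max(score - mean(oob, na.rm = TRUE) + 0.5, 0), 1)
  }
  imp <- fit$variable.importance
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot  # scale so importances sum to 1 per fold
  list(score = score, importance = imp)
}

#' Patient-aware leave-one-out cross-validated classification
#'
#' Trains a random-forest classifier to predict IGHV mutation status from
#' the accessibility matrix, evaluated by leave-one-out cross-validation
#' that removes from every training set all samples belonging to the test
#' sample's patient, eliminating within-patient leakage. Out-of-fold
#' P(mutated) scores are pooled into one ROC curve; per-region Gini
#' (impurity-decrease) importances are normalised to sum to one within
#' each fold and averaged over folds.
#'
#' @param acc An `accessibility_matrix`.
#' @param labels Labels from [ighv_labels()]; `unknown` samples are
#'   excluded.
#' @param patients Named vector or tibble (`sample_id`, `patient_id`)
#'   mapping samples to patients.
#' @param model_config An [rf_config()].
#' @param seed Integer seed; per-fold seeds are derived from it.
#' @param layer Matrix layer to classify on.
#' @return An object of class `loocv_result` with elements `scores`
#'   (per-sample out-of-fold tibble), `roc`, `auc`, `operating_point`,
#'   `importance` (per-region fold-averaged tibble) and `fold_map`.
#' @export
patient_aware_loocv <- function(acc, labels, patients, model_config = rf_config(),
                                seed = 1L, layer = c("normalized", "raw")) {
  x <- acc_layer(acc, match.arg(layer))
  lab <- resolve_labels(labels, colnames(x))
  pat <- resolve_patients(patients, colnames(x))
  keep <- which(lab != "unknown")
  if (length(unique(droplevels(lab[keep]))) < 2) {
    abort("labels are constant: classification needs both classes")
  }
  if (min(table(droplevels(lab[keep]))) < 2) {
    abort("each class needs at least 2 labelled samples")
  }
  xs <- t(x[, keep, drop = FALSE])  # samples x regions
  ys <- droplevels(lab[keep])
  ps <- pat[keep]
  ids <- colnames(x)[keep]

  scores <- numeric(length(ids))
  imp_sum <- numeric(ncol(xs))
  fold_map <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    train <- which(ps != ps[i])
    if (length(unique(ys[train])) < 2) {
      abort(sprintf(
        "class disappears from the training set of the fold testing sample %s; the cohort is too small",
        ids[i]
      ))
    }
    fold <- fit_fold(xs[train, , drop = FALSE], ys[train],
                     xs[i, , drop = FALSE], model_config,
                     seed = derive_seed(seed, i))
    scores[i] <- fold$score
    imp_sum <- imp_sum + fold$importance
    fold_map[[i]] <- ids[train]
  }
  names(fold_map) <- ids
  roc <- roc_and_auc(scores, ys, positive = "mutated")
  structure(list(
    scores = tibble(sample_id = ids, truth = as.character(ys), score = scores),
    roc = roc$roc, auc = roc$auc, operating_point = roc$operating_point,
    importance = tibble(region_id = colnames(xs),
                        importance = imp_sum / length(ids)),
    fold_map = fold_map,
    model_config = model_config, seed = as.integer(seed)
  ), class = "loocv_result")
}

resolve_patients <- function(patients, sample_ids) {
  if (is.data.frame(patients)) {
    if (!all(c("sample_id", "patient_id") %in% names(patients))) {
      abort("patients tibble must have columns sample_id and patient_id")
    }
    v <- setNames(patients$patient_id, patients$sample_id)[sample_ids]
  } else {
    v <- patients
    if (!is.null(names(v))) v <- v[sample_ids]
  }
  if (length(v) != length(sample_ids) || any(is.na(v))) {
    abort("patients must assign every sample to a patient")
  }
  as.character(v)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d samples, AUC %.3f (sens %.3f / spec %.3f at the top-left point)\n",
              nrow(x$scores), x$auc,
              x$operating_point$sensitivity, x$operating_point$specificity))
  invisible(x)
}

#' @describeIn patient_aware_loocv Per-sample out-of-fold scores.
#' @param x A `loocv_result`.
#' @param ... Unused.
#' @export
tidy.loocv_result <- function(x, ...) x$scores

#' @describeIn patient_aware_loocv One-row performance summary.
#' @export
glance.loocv_result <- function(x, ...) {
  tibble(
    auc = x$auc,
    sensitivity = x$operating_point$sensitivity,
    specificity = x$operating_point$specificity,
    n_samples = nrow(x$scores),
    n_regions = nrow(x$importance)
  )
}

#' ROC curve, AUC and top-left operating point
#'
#' Builds the ROC curve by sweeping thresholds over the unique scores. The
#' AUC equals the Mann-Whitney concordance probability, with tied
#' positive/negative score pairs counted one half. The operating point is
#' the ROC point with the smallest Euclidean distance to the top-left
#' corner (FPR 0, TPR 1).
#'
#' @param scores Numeric classification scores (higher = more like the
#'   positive class).
#' @param labels Class labels, same length as `scores`.
#' @param positive Which label value is the positive class.
#' @return A list with `roc` (tibble of `fpr`, `tpr`), `auc`, and
#'   `operating_point` (tibble with `fpr`, `tpr`, `sensitivity`,
#'   `specificity`).
#' @export
roc_and_auc <- function(scores, labels, positive = "mutated") {
  labels <- as.character(labels)
  pos <- labels == positive
  if (all(pos) || !any(pos)) abort("both classes must be present to compute a ROC curve")
  n_pos <- sum(pos); n_neg <- sum(!pos)

  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & pos) / n_pos, 1)
  fpr <- vapply(thresholds, function(t) sum(scores >= t & !pos) / n_neg, 1)
  roc <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1) {
    roc <- bind_rows(roc, tibble(fpr = 1, tpr = 1))
  }

  # Mann-Whitney with the midrank tie convention
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  best <- which.min(d)
  op <- tibble(fpr = roc$fpr[best], tpr = roc$tpr[best],
               sensitivity = roc$tpr[best], specificity = 1 - roc$fpr[best])
  list(roc = roc, auc = auc, operating_point = op)
}

#' Shuffled-label null distribution of the cross-validated AUC
#'
#' Re-runs the full patient-aware leave-one-out cross-validation with class
#' labels randomly shuffled across samples before each repetition (the
#' patient structure is kept for fold exclusion) and records each run's
#' AUC. Under the null the expected AUC is 0.5. Permutations in which a
#' fold fails (a class vanishing from some training set) are recorded and
#' skipped.
#'
#' @inheritParams patient_aware_loocv
#' @param n_permutations Number of shuffled-label repetitions.
#' @return An object of class `null_distribution`: tibble of `permutation`,
#'   `auc`, with failures and the seed in attributes.
#' @export
shuffled_label_null <- function(acc, labels, patients, n_permutations = 1000,
                                seed = 1L, model_config = rf_config(),
                                layer = c("normalized", "raw")) {
  layer <- match.arg(layer)
  x <- acc_layer(acc, layer)
  lab <- resolve_labels(labels, colnames(x))
  keep <- colnames(x)[lab != "unknown"]
  lab_keep <- as.character(lab[lab != "unknown"])

  aucs <- rep(NA_real_, n_permutations)
  failures <- character()
  for (perm in seq_len(n_permutations)) {
    shuffled <- withr::with_seed(derive_seed(seed, 100000 + perm),
                                 sample(lab_keep))
    perm_labels <- tibble(sample_id = keep,
                          ighv_label = factor(shuffled, levels = levels(lab)))
    res <- tryCatch(
      patient_aware_loocv(acc, perm_labels, patients,
                          model_config = model_config,
                          seed = derive_seed(seed, perm), layer = layer),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("permutation %d: %s", perm, conditionMessage(res)))
    } else {
      aucs[perm] <- res$auc
    }
  }
  out <- tibble(permutation = seq_len(n_permutations), auc = aucs) |>
    filter(!is.na(auc))
  structure(out, class = c("null_distribution", class(tibble())),
            n_permutations = n_permutations, seed = as.integer(seed),
            failures = failures)
}

#' @describeIn shuffled_label_null One-row summary of the null AUCs.
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(
    n_permutations = attr(x, "n_permutations"),
    n_completed = nrow(x),
    mean_auc = mean(x$auc),
    sd_auc = sd(x$auc),
    q95_auc = quantile(x$auc, 0.95, names = FALSE)
  )
}

#' Extract signature regions from a cross-validated classifier
#'
#' Retains regions whose fold-averaged Gini importance exceeds the
#' threshold and assigns each a direction by comparing its group means on
#' the matrix: cluster 1 collects the regions more accessible in the
#' mutated subtype, cluster 2 those more accessible in the unmutated
#' subtype.
#'
#' @param result A `loocv_result`.
#' @param acc The `accessibility_matrix` the classifier was trained on.
#' @param labels Labels used for training.
#' @param importance_threshold Retain regions with mean importance strictly
#'   above this value.
#' @param layer Matrix layer for direction assignment.
#' @return A tibble of class `signature_regions`: `region_id`,
#'   `importance`, `higher_in`, `cluster`; the threshold is stored as an
#'   attribute. Empty (with a warning) when nothing passes.
#' @export
extract_signature <- function(result, acc, labels, importance_threshold = 1e-4,
                              layer = c("normalized", "raw")) {
  if (!inherits(result, "loocv_result")) abort("result must be a loocv_result")
  x <- acc_layer(acc, match.arg(layer))
  lab <- resolve_labels(labels, colnames(x))
  keep_regions <- result$importance |> filter(importance > importance_threshold)
  if (nrow(keep_regions) == 0) {
    warn("no region exceeds the importance threshold; returning an empty signature")
    out <- tibble(region_id = character(), importance = numeric(),
                  higher_in = character(), cluster = integer())
    return(structure(out, class = c("signature_regions", class(tibble())),
                     importance_threshold = importance_threshold))
  }
  m1 <- unname(rowMeans(x[keep_regions$region_id, lab == "mutated", drop = FALSE]))
  m2 <- unname(rowMeans(x[keep_regions$region_id, lab == "unmutated", drop = FALSE]))
  out <- keep_regions |>
    mutate(higher_in = ifelse(m1 >= m2, "mutated", "unmutated"),
           cluster = ifelse(m1 >= m2, 1L, 2L)) |>
    arrange(desc(importance))
  structure(out, class = c("signature_regions", class(tibble())),
            importance_threshold = importance_threshold)
}
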