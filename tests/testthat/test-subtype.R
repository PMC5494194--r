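test_that("IGHV labels follow the strict >98% homology rule", {
  sheet <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    ighv_homology = c(97.5, 99.2, 98.0, NA)
  )
  lab <- ighv_labels(sheet)
  expect_equal(as.character(lab$ighv_label),
               c("mutated", "unmutated", "mutated", "unknown"))
  expect_error(ighv_labels(tibble::tibble(sample_id = "a", ighv_homology = 104)),
               "\\[0, 100\\]")
})

test_that("the variance F test matches its closed form and var.test", {
  m <- rbind(c(1, 5, 9, 4, 5, 6))
  dimnames(m) <- list("r1", paste0("s", 1:6))
  acc <- new_acc_for_test(m)
  lab <- tibble::tibble(sample_id = paste0("s", 1:6),
                        ighv_label = rep(c("mutated", "unmutated"), each = 3))
  dv <- differential_variability(acc, lab, layer = "raw")
  # var(1,5,9) = 16, var(4,5,6) = 1; F(2,2) upper tail is 1/(1+x)
  expect_equal(dv$f_stat, 16)
  expect_equal(dv$p_value, 2 * (1 / 17))
  expect_equal(dv$higher_group, "mutated")

  # agreement with var.test across random draws
  withr::with_seed(21, {
    for (rep in 1:25) {
      x <- matrix(rnorm(10 * 9, sd = rep(c(1, 2), length.out = 10)), 10, 9,
                  dimnames = list(paste0("r", 1:10), paste0("s", 1:9)))
      lab9 <- tibble::tibble(
        sample_id = paste0("s", 1:9),
        ighv_label = c(rep("mutated", 4), rep("unmutated", 5))
      )
      dvr <- differential_variability(new_acc_for_test(x), lab9, layer = "raw")
      for (i in 1:10) {
        vt <- var.test(x[i, 1:4], x[i, 5:9])
        expect_equal(dvr$f_stat[i], unname(vt$statistic))
        expect_equal(dvr$p_value[i], vt$p.value)
      }
    }
  })
})

test_that("degenerate variance rows are flagged, not significant", {
  m <- rbind(const = c(3, 3, 3, 3, 3, 3),
             onezero = c(2, 2, 2, 1, 5, 9))
  colnames(m) <- paste0("s", 1:6)
  lab <- tibble::tibble(sample_id = paste0("s", 1:6),
                        ighv_label = rep(c("mutated", "unmutated"), each = 3))
  dv <- differential_variability(new_acc_for_test(m), lab, layer = "raw")
  expect_equal(dv$flag, c("skipped_zero_variance", "one_group_zero_variance"))
  expect_false(dv$significant[1])
  expect_true(is.na(dv$p_value[1]))
  expect_equal(dv$p_value[2], 0)
  expect_equal(attr(dv, "n_tested"), 1L)
  # the mean>1 gate blocks significance of low-signal regions
  expect_true(dv$mean[2] > 1)  # sanity: this fixture passes the gate
  g <- glance(dv)
  expect_equal(g$n_skipped, 1L)
})

test_that("ROC/AUC follows the Mann-Whitney tie convention", {
  lab <- c("m", "m", "u", "u")
  r1 <- roc_and_auc(c(0.9, 0.8, 0.1, 0.2), lab, positive = "m")
  expect_equal(r1$auc, 1)
  expect_equal(r1$operating_point$sensitivity, 1)
  expect_equal(r1$operating_point$specificity, 1)
  expect_equal(r1$roc$fpr[1], 0)
  expect_equal(r1$roc$tpr[nrow(r1$roc)], 1)

  expect_equal(roc_and_auc(rep(0.5, 4), lab, positive = "m")$auc, 0.5)

  # concordant-pair worked example: 3 of 4 pairs concordant
  r2 <- roc_and_auc(c(0.9, 0.8, 0.85, 0.1), c("m", "m", "u", "u"), positive = "m")
  expect_equal(r2$auc, 3 / 4)

  expect_error(roc_and_auc(1:3, c("m", "m", "m"), positive = "m"), "both classes")

  withr::with_seed(17, {
    for (rep in 1:100) {
      n <- sample(6:20, 1)
      y <- sample(c("m", "u"), n, replace = TRUE, prob = c(0.5, 0.5))
      if (length(unique(y)) < 2) y[1:2] <- c("m", "u")
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
      res <- roc_and_auc(s, y, positive = "m")
      expect_equal(res$auc, auc_oracle(s, y, "m"))
      expect_true(all(diff(res$roc$fpr) >= 0) && all(diff(res$roc$tpr) >= 0))
    }
  })

  skip_if_not_installed("pROC")
  withr::with_seed(18, {
    y <- sample(c("m", "u"), 30, replace = TRUE); y[1:2] <- c("m", "u")
    s <- runif(30)
    expect_equal(
      roc_and_auc(s, y, positive = "m")$auc,
      as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                     levels = c("u", "m"), direction = "<",
                                     quiet = TRUE)))
    )
  })
})

test_that("patient-aware LOOCV never trains on the test sample's patient", {
  co <- tiny_cohort()
  acc <- quantile_normalize(cohort_matrix(co))
  lab <- ighv_labels(co$sample_sheet)
  fit <- patient_aware_loocv(acc, lab, co$sample_sheet[, c("sample_id", "patient_id")],
                             model_config = rf_config(num_trees = 30), seed = 2)
  patient_of <- setNames(co$sample_sheet$patient_id, co$sample_sheet$sample_id)
  for (test_sample in names(fit$fold_map)) {
    train <- fit$fold_map[[test_sample]]
    expect_false(test_sample %in% train)
    expect_false(patient_of[test_sample] %in% patient_of[train])
  }
  # every labelled sample scored exactly once
  expect_identical(sort(fit$scores$sample_id),
                   sort(co$sample_sheet$sample_id[lab$ighv_label != "unknown"]))
  expect_false(anyDuplicated(fit$scores$sample_id) > 0)
  # fold-averaged importances are normalised per fold, hence sum to <= 1
  expect_lte(sum(fit$importance$importance), 1 + 1e-8)

  # constant labels fail loudly
  const <- tibble::tibble(sample_id = co$sample_sheet$sample_id,
                          ighv_label = "mutated")
  expect_error(patient_aware_loocv(acc, const,
                                   co$sample_sheet[, c("sample_id", "patient_id")]),
               "both classes|constant")
})

test_that("shuffled-label null machinery works at n_permutations = 1", {
  co <- tiny_cohort()
  acc <- quantile_normalize(cohort_matrix(co))
  lab <- ighv_labels(co$sample_sheet)
  nd <- shuffled_label_null(acc, lab, co$sample_sheet[, c("sample_id", "patient_id")],
                            n_permutations = 1, seed = 3,
                            model_config = rf_config(num_trees = 20))
  expect_equal(nrow(nd), 1)
  expect_true(nd$auc >= 0 && nd$auc <= 1)
  g <- glance(nd)
  expect_equal(g$n_completed, 1L)
})

test_that("signature extraction applies the importance threshold strictly", {
  co <- tiny_cohort()
  acc <- quantile_normalize(cohort_matrix(co))
  lab <- ighv_labels(co$sample_sheet)
  fake <- structure(list(
    importance = tibble::tibble(region_id = rownames(acc$raw)[1:2],
                                importance = c(2e-4, 5e-5)),
    scores = tibble::tibble()
  ), class = "loocv_result")
  sig <- extract_signature(fake, acc, lab)
  expect_equal(sig$region_id, rownames(acc$raw)[1])

  fake$importance$importance <- c(0, 0)
  expect_warning(sig0 <- extract_signature(fake, acc, lab), "empty")
  expect_equal(nrow(sig0), 0)

  # directions come from group means on the chosen layer
  fake2 <- structure(list(
    importance = tibble::tibble(region_id = c("up_m", "up_u"),
                                importance = c(1e-2, 1e-2))
  ), class = "loocv_result")
  lab4 <- tibble::tibble(sample_id = paste0("s", 1:4),
                         ighv_label = c("mutated", "mutated", "unmutated", "unmutated"))
  m2 <- matrix(c(10, 1, 9, 2, 1, 10, 2, 9), nrow = 2,
               dimnames = list(c("up_m", "up_u"), paste0("s", 1:4)))
  sig2 <- extract_signature(fake2, new_acc_for_test(m2), lab4, layer = "raw")
  expect_equal(sig2$cluster[sig2$region_id == "up_m"], 1L)
  expect_equal(sig2$cluster[sig2$region_id == "up_u"], 2L)
})

test_that("correlation clustering recovers block structure and duplicates", {
  base1 <- c(1, 5, 2, 8, 3)
  base2 <- c(9, 2, 7, 1, 6)
  m <- cbind(a1 = base1, a2 = base1 + 0.01, b1 = base2, b2 = base2 - 0.01)
  rownames(m) <- paste0("r", 1:5)
  cl <- cluster_samples(new_acc_for_test(m), k = 2, layer = "raw")
  expect_equal(cl$cluster[cl$sample_id == "a1"], cl$cluster[cl$sample_id == "a2"])
  expect_equal(cl$cluster[cl$sample_id == "b1"], cl$cluster[cl$sample_id == "b2"])
  expect_false(cl$cluster[cl$sample_id == "a1"] == cl$cluster[cl$sample_id == "b1"])

  # a duplicated sample sits at distance zero from its twin
  m_dup <- cbind(m, a1_copy = m[, "a1"])
  cl2 <- cluster_samples(new_acc_for_test(m_dup), k = 2, layer = "raw")
  expect_equal(cl2$cluster[cl2$sample_id == "a1"],
               cl2$cluster[cl2$sample_id == "a1_copy"])

  m_const <- cbind(m, flat = rep(1, 5))
  expect_error(cluster_samples(new_acc_for_test(m_const), k = 2, layer = "raw"),
               "flat")
})

test_that("intermediate samples form their own cluster in most seeds", {
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(tiny_spec(
      n_samples = 15, n_patients = 12, intermediate_fraction = 0.3,
      n_core_regions = 60, n_variable_regions = 0,
      n_sample_specific_regions_per_sample = 0,
      n_signature_regions = 40, signature_log2_effect = 3,
      dispersion = 0.02, n_genes = 10, seed = 100 + s
    ))
    acc <- quantile_normalize(cohort_matrix(co))
    sig_ids <- co$ground_truth$signature_regions$region_id
    cl <- cluster_samples(acc, regions = sig_ids, k = 3)
    truth <- setNames(co$ground_truth$labels$subtype,
                      co$ground_truth$labels$sample_id)
    tab <- table(truth[cl$sample_id], cl$cluster)
    # intermediates own a cluster: some cluster contains all intermediates
    # and nothing else
    int_n <- sum(truth == "intermediate")
    ok <- any(tab["intermediate", ] == int_n & colSums(tab) == int_n)
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("PCA projections explain variance in the documented way", {
  # variation along one direction only: PC1 explains everything
  m <- outer(c(1, 2, 3), c(0, 1, 2, 3)) + 5
  dimnames(m) <- list(paste0("r", 1:3), paste0("s", 1:4))
  p <- pca_projection(new_acc_for_test(m), n_components = 3, layer = "raw")
  ev <- attr(p, "explained_variance")
  expect_equal(ev[1], 1)
  expect_true(all(diff(ev) <= 1e-12))

  # planted two-subtype cohort: PC1 separates the groups
  co <- generate_cohort(tiny_spec(
    n_samples = 16, n_patients = 12, n_core_regions = 120,
    n_variable_regions = 0, n_sample_specific_regions_per_sample = 0,
    n_signature_regions = 50, signature_log2_effect = 2, n_genes = 10,
    seed = 77
  ))
  acc <- quantile_normalize(cohort_matrix(co))
  p2 <- pca_projection(acc, n_components = 2)
  truth <- setNames(co$ground_truth$labels$subtype,
                    co$ground_truth$labels$sample_id)
  auc <- auc_oracle(p2$PC1, truth[p2$sample_id], "mutated")
  expect_gte(max(auc, 1 - auc), 0.9)

  expect_error(pca_projection(new_acc_for_test(
    matrix(1, 2, 2, dimnames = list(c("r1", "r2"), c("a", "b")))), layer = "raw"),
    "degenerate|constant")
})
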