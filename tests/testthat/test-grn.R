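toy_genes <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 50000L),
    body_start = c(10000L, 46001L), body_end = c(14000L, 50001L)
  )
}

test_that("TF filtering applies strict purity and site-count thresholds", {
  peaks <- iv("chr1", 0, 100000)
  mk_sites <- function(tf, n, purity) {
    iv("chr1", seq(100, by = 50, length.out = n),
       seq(100, by = 50, length.out = n) + 10, tf = tf, purity = purity)
  }
  sites <- dplyr::bind_rows(
    mk_sites("keep", 500, 0.71),     # exactly min_sites qualifying: retained
    mk_sites("short", 499, 0.9),     # one too few: excluded
    mk_sites("border", 500, 0.7)     # purity exactly at threshold: none qualify
  )
  res <- filter_tfs(sites, peaks, min_sites = 500, purity_min = 0.7)
  expect_identical(res$retained_tfs, "keep")
  expect_equal(nrow(res$sites), 500)
  expect_true(all(res$sites$purity > 0.7))
  expect_equal(res$summary$n_qualifying[res$summary$tf == "border"], 0L)

  # off-peak sites never qualify
  off <- mk_sites("keep", 10, 0.99) |>
    dplyr::mutate(chrom = "chr2")
  res2 <- filter_tfs(dplyr::bind_rows(sites, off), peaks, min_sites = 500)
  expect_equal(res2$summary$n_qualifying[res2$summary$tf == "keep"], 500L)

  expect_error(filter_tfs(sites, peaks[0, ]), "empty")
})

test_that("site-to-gene assignment handles body, upstream and nearest classes", {
  genes <- toy_genes()
  sites <- dplyr::bind_rows(
    iv("chr1", 12000, 12010, tf = "t", purity = 0.9),  # inside G1 body
    iv("chr1", 7995, 8005, tf = "t", purity = 0.9),    # 2,000 bp upstream of G1 (+)
    iv("chr1", 51995, 52005, tf = "t", purity = 0.9),  # 2,000 bp upstream of G2 (-)
    iv("chr1", 25000, 25010, tf = "t", purity = 0.9),  # intergenic, nearer G1
    iv("chr2", 100, 110, tf = "t", purity = 0.9)       # chromosome without genes
  )
  asg <- assign_sites_to_genes(sites, genes)
  expect_equal(asg$class, c("body", "upstream", "upstream",
                            "intergenic_nearest", "unassigned"))
  expect_equal(asg$gene_id[1:4], c("G1", "G1", "G2", "G1"))
  expect_equal(asg$distance[2], 2000)
  expect_equal(asg$distance[3], 2000)
  expect_true(is.na(asg$gene_id[5]))

  # a site just beyond the 2,500 bp upstream window is intergenic
  far <- iv("chr1", 7400, 7410, tf = "t", purity = 0.9)
  expect_equal(assign_sites_to_genes(far, genes)$class, "intergenic_nearest")

  # overlapping gene models: body/upstream hits multi-assign
  genes2 <- dplyr::bind_rows(
    genes,
    tibble::tibble(gene_id = "G3", chrom = "chr1", strand = "+",
                   tss = 11000L, body_start = 11000L, body_end = 15000L)
  )
  asg2 <- assign_sites_to_genes(iv("chr1", 12000, 12010, tf = "t", purity = 0.9),
                                genes2)
  expect_setequal(asg2$gene_id, c("G1", "G3"))
})

test_that("intergenic nearest assignment matches exhaustive search", {
  withr::with_seed(23, {
    for (rep in 1:100) {
      g <- tibble::tibble(
        gene_id = sprintf("g%d", 1:6), chrom = "chr1",
        strand = sample(c("+", "-"), 6, replace = TRUE),
        tss = sample(seq(5000, 95000, by = 500), 6)
      ) |>
        dplyr::mutate(body_start = ifelse(strand == "+", tss, tss - 99L),
                      body_end = ifelse(strand == "+", tss + 100L, tss + 1L))
      s_start <- sample(0:99000, 30)
      sites <- iv("chr1", s_start, s_start + 10, tf = "t", purity = 0.9)
      asg <- assign_sites_to_genes(sites, g)
      inter <- asg[asg$class == "intergenic_nearest", ]
      for (i in seq_len(nrow(inter))) {
        mid <- (inter$start[i] + inter$end[i]) / 2
        d <- abs(g$tss - mid)
        expect_equal(inter$distance[i], min(d))
        expect_equal(inter$gene_id[i], sort(g$gene_id[d == min(d)])[1])
      }
    }
  })
})

test_that("interaction scores are the stated additive purity-distance sums", {
  asg1 <- tibble::tibble(tf = "t", gene_id = "g", purity = 1, distance = 0)
  expect_equal(interaction_scores(asg1)$score, 1)

  # purity at chance level contributes nothing
  asg0 <- tibble::tibble(tf = "t", gene_id = "g", purity = 0.5, distance = 0)
  expect_equal(interaction_scores(asg0)$score, 0)

  # megabase distance decays the weight tenfold
  asg_d <- tibble::tibble(tf = "t", gene_id = "g", purity = 1, distance = 1e6)
  expect_equal(interaction_scores(asg_d)$score, 0.1)

  withr::with_seed(5, {
    for (rep in 1:100) {
      n <- sample(2:12, 1)
      asg <- tibble::tibble(
        tf = sample(c("t1", "t2"), n, replace = TRUE),
        gene_id = sample(c("ga", "gb"), n, replace = TRUE),
        purity = runif(n, 0.5, 1),
        distance = runif(n, 0, 2e6)
      )
      sc <- interaction_scores(asg)
      # independent site-by-site re-summation
      oracle <- aggregate(
        2 * (asg$purity - 0.5) * 10^(-asg$distance / 1e6),
        by = list(tf = asg$tf, gene_id = asg$gene_id), FUN = sum
      )
      for (i in seq_len(nrow(oracle))) {
        got <- sc$score[sc$tf == oracle$tf[i] & sc$gene_id == oracle$gene_id[i]]
        expect_equal(got, oracle$x[i])
      }
      # additivity: splitting the sites and summing partial scores agrees
      half <- seq_len(floor(n / 2))
      sc_a <- interaction_scores(asg[half, , drop = FALSE])
      sc_b <- interaction_scores(asg[-half, , drop = FALSE])
      merged <- dplyr::bind_rows(sc_a, sc_b) |>
        dplyr::group_by(tf, gene_id) |>
        dplyr::summarise(score = sum(score), .groups = "drop")
      joined <- dplyr::left_join(sc, merged, by = c("tf", "gene_id"))
      expect_equal(joined$score.x, joined$score.y)
    }
  })

  # monotonicity: raising purity or lowering distance never lowers the score
  base <- tibble::tibble(tf = "t", gene_id = "g",
                         purity = c(0.8, 0.6), distance = c(1000, 5e5))
  s0 <- interaction_scores(base)$score
  up_p <- base; up_p$purity[1] <- 0.95
  dn_d <- base; dn_d$distance[2] <- 1e5
  expect_gte(interaction_scores(up_p)$score, s0)
  expect_gte(interaction_scores(dn_d)$score, s0)
})

test_that("network construction applies the strict edge threshold", {
  sc <- tibble::tibble(tf = c("t1", "t1"), gene_id = c("g1", "g2"),
                       score = c(1.2, 0.9))
  net <- build_network(sc)
  expect_equal(net$n_edges, 1)
  expect_equal(net$edges$gene_id, "g1")

  empty <- build_network(dplyr::mutate(sc, score = c(1, 0.3)))
  expect_equal(empty$n_edges, 0)
  expect_equal(nrow(empty$nodes), 0)

  # handshake identity: out-degrees and in-degrees both sum to edge count
  withr::with_seed(6, {
    sc2 <- tibble::tibble(
      tf = sample(paste0("t", 1:4), 30, replace = TRUE),
      gene_id = sample(paste0("g", 1:8), 30, replace = TRUE),
      score = runif(30, 0, 3)
    ) |> dplyr::distinct(tf, gene_id, .keep_all = TRUE)
    net2 <- build_network(sc2)
    expect_equal(sum(net2$nodes$degree[grepl("^t", net2$nodes$node)]), net2$n_edges)
    expect_equal(sum(net2$nodes$degree[grepl("^g", net2$nodes$node)]), net2$n_edges)
    g <- glance(net2)
    expect_equal(g$n_edges, net2$n_edges)
  })
})

test_that("differential connectivity is normalised, antisymmetric, scale-free", {
  mk_net <- function(edges) build_network(dplyr::mutate(edges, score = 2))
  a <- mk_net(tibble::tibble(
    tf = c("t1", "t1", "t2", "t2", "t2", "t3", "t3", "t3", "t3", "t4"),
    gene_id = paste0("g", 1:10)
  ))
  b <- mk_net(tibble::tibble(
    tf = c("t1", "t2", "t2", "t2", "t3", "t3", "t3", "t3", "t4", "t4"),
    gene_id = paste0("g", 1:10)
  ))
  dc <- differential_connectivity(a, b)
  # t1: degree 2/10 in A vs 1/10 in B -> log2 change 1
  expect_equal(dc$shared$log2_change[dc$shared$node == "t1"], 1)
  # identical networks: all changes zero
  dc_same <- differential_connectivity(a, a)
  expect_true(all(dc_same$shared$log2_change == 0))
  # antisymmetry
  dc_rev <- differential_connectivity(b, a)
  both <- dplyr::inner_join(dc$shared, dc_rev$shared, by = "node")
  expect_equal(both$log2_change.x, -both$log2_change.y)
  # doubling every edge of A leaves all changes unchanged
  a2 <- mk_net(dplyr::bind_rows(tidy(a) |> dplyr::select(tf, gene_id),
                                tidy(a) |> dplyr::mutate(gene_id = paste0(gene_id, "_dup")) |>
                                  dplyr::select(tf, gene_id)))
  dc2 <- differential_connectivity(a2, b)
  shared_tfs <- intersect(dc$shared$node, dc2$shared$node)
  for (nd in paste0("t", 1:4)) {
    expect_equal(dc2$shared$log2_change[dc2$shared$node == nd],
                 dc$shared$log2_change[dc$shared$node == nd])
  }
})

test_that("planted regulatory edges are recovered and decoys rejected", {
  co <- tiny_cohort()
  cons <- merge_peak_sets(co$peaks)
  filtered <- filter_tfs(co$footprints, cons, min_sites = 40)
  expect_true(all(sprintf("TF%02d", 1:2) %in% filtered$retained_tfs))
  expect_false(any(grepl("^DTF", filtered$retained_tfs)))

  asg <- assign_sites_to_genes(filtered$sites, co$gene_models)
  net <- build_network(interaction_scores(asg))
  key <- function(d) paste(d$tf, d$gene_id)
  planted_hit <- key(co$ground_truth$planted_edges) %in% key(net$edges)
  decoy_hit <- key(co$ground_truth$decoy_edges) %in% key(net$edges)
  expect_gte(mean(planted_hit), 0.9)
  expect_lte(mean(decoy_hit), 0.1)
})
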