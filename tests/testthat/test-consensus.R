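test_that("merging peak sets produces the interval union", {
  # single set passes through unchanged
  one <- iv("chr1", c(0, 200), c(100, 300), sample_id = "a")
  m <- merge_peak_sets(one)
  expect_equal(m$start, c(0L, 200L))
  expect_equal(m$end, c(100L, 300L))

  # overlapping intervals fuse
  two <- dplyr::bind_rows(one, iv("chr1", 50, 150, sample_id = "b"))
  m <- merge_peak_sets(two)
  expect_equal(m$start, c(0L, 200L))
  expect_equal(m$end, c(150L, 300L))

  # book-ended intervals merge (distance-0 merge)
  be <- dplyr::bind_rows(iv("chr1", 0, 100, sample_id = "a"),
                         iv("chr1", 100, 200, sample_id = "b"))
  m <- merge_peak_sets(be)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 200L))

  expect_error(merge_peak_sets(list()), "empty")
  expect_error(merge_peak_sets(iv("chr1", 10, 10, sample_id = "a")), "start >= end")
})

test_that("merge agrees with per-base union marking on random instances", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      n <- sample(1:12, 1)
      x <- tibble::tibble(
        sample_id = sample(letters[1:3], n, replace = TRUE),
        chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
        start = sample(0:900, n, replace = TRUE)
      ) |>
        dplyr::mutate(end = start + sample(1:120, n, replace = TRUE))
      m <- merge_peak_sets(x)
      oracle <- union_oracle(x, chrom_len = 1100)
      expect_equal(as.data.frame(m[, c("chrom", "start", "end")]),
                   as.data.frame(oracle), ignore_attr = TRUE)
    }
  })
})

test_that("merge is idempotent and order-invariant", {
  co <- tiny_cohort()
  m1 <- merge_peak_sets(co$peaks)
  m2 <- merge_peak_sets(m1 |> dplyr::mutate(sample_id = "merged"))
  expect_equal(as.data.frame(m1[, c("chrom", "start", "end")]),
               as.data.frame(m2[, c("chrom", "start", "end")]), ignore_attr = TRUE)
  shuffled <- withr::with_seed(1, co$peaks[sample.int(nrow(co$peaks)), ])
  m3 <- merge_peak_sets(shuffled)
  expect_equal(as.data.frame(m1[, c("chrom", "start", "end")]),
               as.data.frame(m3[, c("chrom", "start", "end")]), ignore_attr = TRUE)
})

test_that("an exclusion list removes peaks before merging", {
  pk <- dplyr::bind_rows(iv("chr1", 0, 100, sample_id = "a"),
                         iv("chr1", 500, 600, sample_id = "a"))
  m <- merge_peak_sets(pk, exclude = iv("chr1", 90, 120))
  expect_equal(m$start, 500L)
})

test_that("saturation curves behave as the exhaustive oracle dictates", {
  # identical single peak in both samples: flat curve, zero-width band
  pk <- dplyr::bind_rows(iv("chr1", 0, 100, sample_id = "a"),
                         iv("chr1", 0, 100, sample_id = "b"))
  s <- saturation_curve(pk, n_iterations = 10, seed = 3)
  expect_equal(s$mean, c(1, 1))
  expect_equal(s$ci_low, s$ci_high)

  # disjoint peaks: final value 3 under every ordering
  pk3 <- dplyr::bind_rows(iv("chr1", 0, 100, sample_id = "a"),
                          iv("chr1", 200, 300, sample_id = "b"),
                          iv("chr1", 400, 500, sample_id = "c"))
  s3 <- saturation_curve(pk3, n_iterations = 25, seed = 3)
  expect_equal(s3$mean[3], 3)
  expect_equal(s3$ci_low[3], 3)
  expect_equal(s3$ci_high[3], 3)

  # toy with one shared + one unique region per sample: compare the mean
  # curve against the average over all 6 orderings, enumerated exhaustively
  shared <- iv("chr1", 0, 100)
  toy <- dplyr::bind_rows(
    dplyr::bind_rows(shared, iv("chr1", 200, 300)) |> dplyr::mutate(sample_id = "a"),
    dplyr::bind_rows(shared, iv("chr1", 400, 500)) |> dplyr::mutate(sample_id = "b"),
    dplyr::bind_rows(shared, iv("chr1", 600, 700)) |> dplyr::mutate(sample_id = "c")
  )
  sets <- split(toy[, c("chrom", "start", "end")], toy$sample_id)
  n_regions_of <- function(samples) {
    nrow(merge_peak_sets(dplyr::bind_rows(sets[samples]) |>
                           dplyr::mutate(sample_id = "x")))
  }
  perms <- list(c("a","b","c"), c("a","c","b"), c("b","a","c"),
                c("b","c","a"), c("c","a","b"), c("c","b","a"))
  oracle_curves <- sapply(perms, function(p) {
    sapply(1:3, function(k) n_regions_of(p[1:k]))
  })
  s_toy <- saturation_curve(toy, n_iterations = 400, seed = 9)
  expect_equal(s_toy$mean, rowMeans(oracle_curves), tolerance = 0.05)
  expect_equal(s_toy$mean[3], 4)
})

test_that("saturation curves are monotone and end at the consensus size", {
  co <- tiny_cohort()
  s <- saturation_curve(co$peaks, n_iterations = 20, seed = 2)
  expect_true(all(diff(s$mean) >= 0))
  expect_true(all(s$ci_low <= s$mean + 1e-12) && all(s$mean <= s$ci_high + 1e-12))
  expect_equal(s$mean[nrow(s)], nrow(merge_peak_sets(co$peaks)))
  expect_equal(s$ci_low[nrow(s)], s$ci_high[nrow(s)])
})

test_that("region support counts samples with an overlapping peak", {
  pk <- dplyr::bind_rows(
    iv("chr1", c(0, 200), c(100, 300), sample_id = "a"),
    iv("chr1", 50, 150, sample_id = "b"),
    iv("chr1", 210, 260, sample_id = "c")
  )
  cons <- merge_peak_sets(pk)
  sup <- region_support(cons, pk)
  # region [0,150): a+b; region [200,300): a+c
  expect_equal(sup$support, c(2 / 3, 2 / 3))
  expect_true(all(sup$support >= 1 / 3))  # every region holds >= 1 peak

  # class boundaries recorded and applied
  expect_named(attr(sup, "support_boundaries"), c("constitutive", "rare"))
  co <- tiny_cohort()
  cons_big <- merge_peak_sets(co$peaks)
  sup_big <- region_support(cons_big, co$peaks)
  core_ids <- co$ground_truth$regions$region_id[co$ground_truth$regions$role == "core"]
  expect_true(all(sup_big$support_class[sup_big$region_id %in% core_ids] == "constitutive"))
  own_ids <- co$ground_truth$regions$region_id[co$ground_truth$regions$role == "sample_specific"]
  expect_true(all(sup_big$support_class[sup_big$region_id %in% own_ids] == "rare"))
  expect_true(all(sup_big$support >= 1 / co$spec$n_samples))

  expect_error(region_support(cons_big, pk), "built from")
})

test_that("co-localization frequency and fold change follow the definition", {
  genome <- c(chr1 = 10000)
  # whole-genome class: fold change 1
  regions <- iv("chr1", c(0, 5000), c(200, 5100))
  whole <- iv("chr1", 0, 10000, class = "all")
  expect_equal(co_localization(regions, whole, genome)$fold_change, 1)
  expect_equal(co_localization(regions, whole, genome)$frequency, 1)

  # worked example: 200 bp of regions, 50 bp inside a 1 kb class
  regions2 <- iv("chr1", c(0, 5000), c(100, 5100))
  feats <- iv("chr1", 50, 1050, class = "enh")
  res <- co_localization(regions2, feats, genome)
  expect_equal(res$fold_change, (50 / 200) / (1000 / 10000))
  expect_equal(res$frequency, 0.5)

  # regions entirely inside a 10% class: fold change 10
  res10 <- co_localization(iv("chr1", 100, 300), iv("chr1", 0, 1000, class = "c"),
                           genome)
  expect_equal(res10$fold_change, 10)

  expect_error(co_localization(regions2, feats, c(chr1 = 0)), "positive")
})

test_that("fold change calibrates to one for uniformly placed features", {
  genome <- c(chr1 = 1e6)
  regions <- iv("chr1", seq(0, 9e5, by = 1e4), seq(0, 9e5, by = 1e4) + 500)
  folds <- withr::with_seed(8, replicate(200, {
    s <- sample(0:(1e6 - 2000), 40)
    f <- iv("chr1", s, s + 2000, class = "rand")
    co_localization(regions, f, genome)$fold_change
  }))
  expect_lt(abs(mean(folds) - 1), 0.1)
})

test_that("nearest-TSS annotation matches brute force and handles edge cases", {
  genes <- tibble::tibble(
    gene_id = c("G2", "G1"), chrom = "chr1", strand = c("+", "-"),
    tss = c(1000L, 1000L)
  )
  # tie at equal distance: lexicographically smallest gene ID wins
  ann <- annotate_nearest_tss(iv("chr1", 900, 1100), genes)
  expect_equal(ann$gene_id, "G1")
  expect_equal(ann$distance, 0)  # TSS inside the region

  ann2 <- annotate_nearest_tss(iv("chr1", 1400, 1600), genes)
  expect_equal(ann2$distance, 500)

  # region on a chromosome without genes
  ann3 <- annotate_nearest_tss(iv("chrX", 0, 100), genes)
  expect_true(is.na(ann3$gene_id))

  withr::with_seed(12, {
    for (rep in 1:100) {
      g <- tibble::tibble(
        gene_id = sprintf("g%02d", 1:5), chrom = "chr1",
        strand = sample(c("+", "-"), 5, replace = TRUE),
        tss = sample(0:5000, 5)
      )
      r_start <- sample(0:4800, 20)
      r <- iv("chr1", r_start, r_start + sample(10:200, 20, replace = TRUE))
      ann <- annotate_nearest_tss(r, g)
      mid <- (r$start + r$end) / 2
      for (i in 1:20) {
        d <- abs(g$tss - mid[i])
        d[g$tss >= r$start[i] & g$tss < r$end[i]] <- 0
        expect_equal(ann$distance[i], min(d))
        best <- sort(g$gene_id[d == min(d)])[1]
        expect_equal(ann$gene_id[i], best)
      }
    }
  })
})
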