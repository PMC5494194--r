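#' Generate a synthetic ATAC-seq cohort
#'
#' Draws a complete synthetic cohort — per-sample peak sets, fragments, a
#' count matrix, sample sheet, gene models and a transcription-factor
#' footprint table — from a [cohort_spec()]. All planted structure
#' (subtype labels including intermediates, signature and diff-var region
#' identities, planted and decoy TF-to-gene pairs, and the expectation
#' parameters of every count) is recorded in `$ground_truth`.
#'
#' Regeneration with the same spec (including the seed) is bit-identical.
#' Fragments are placed so that counting fragments over the region universe
#' reproduces the drawn count matrix exactly; per-sample fragment totals are
#' recorded as total filtered reads for normalisation.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `spec`, `peaks`, `fragments`, `counts`, `totals`, `sample_sheet`,
#'   `gene_models`, `footprints` and `ground_truth`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("spec must be a cohort_spec object")
  validate_cohort_spec(spec)
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  universe <- build_region_universe(spec)
  cohort_design <- build_sample_design(spec)
  labels <- cohort_design$labels

  params <- build_count_params(spec, universe, labels)
  counts <- draw_counts(params$mu, params$size)
  dimnames(counts) <- list(universe$region_id, labels$sample_id)

  peaks <- build_peak_sets(universe, params$present, labels$sample_id)
  fragments <- build_fragments(spec, universe, counts)
  totals <- vapply(split(fragments$sample_id, fragments$sample_id), length, 1L)
  totals <- totals[labels$sample_id]
  totals[is.na(totals)] <- 0L
  names(totals) <- labels$sample_id

  gene_models <- build_gene_models(spec, universe)
  fp <- build_footprints(spec, universe, gene_models)

  sample_sheet <- labels |>
    transmute(sample_id, patient_id, ighv_homology,
              total_filtered_reads = unname(totals[sample_id]))

  structure(list(
    spec = spec,
    peaks = peaks,
    fragments = fragments,
    counts = counts,
    totals = totals,
    sample_sheet = sample_sheet,
    gene_models = gene_models,
    footprints = fp$sites,
    ground_truth = list(
      labels = labels,
      regions = universe,
      signature_regions = universe |>
        filter(!is.na(.data$higher_in)) |>
        select(region_id, higher_in = "higher_in"),
      diffvar_regions = universe |>
        filter(!is.na(.data$higher_var_in)) |>
        select(region_id, higher_var_in = "higher_var_in"),
      planted_edges = fp$planted_edges,
      decoy_edges = fp$decoy_edges,
      expected_mean = params$mu,
      expected_size = params$size
    )
  ), class = "synthetic_cohort")
}

# ---- region universe -------------------------------------------------------

build_region_universe <- function(spec) {
  m_total <- n_universe_regions(spec)
  alloc <- allocate_regions(spec$genome, m_total)
  chroms <- names(spec$genome)
  pieces <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    m <- alloc[i]
    if (m == 0) next
    spacing <- floor(spec$genome[i] / m)
    offset <- floor((spacing - spec$region_length) / 2)
    start <- (seq_len(m) - 1) * spacing + offset
    pieces[[i]] <- tibble(chrom = chroms[i], start = as.integer(start),
                          end = as.integer(start + spec$region_length))
  }
  universe <- bind_rows(pieces)
  stopifnot(all(universe$start >= 0),
            all(universe$end <= spec$genome[universe$chrom]))
  universe$region_id <- region_id_string(universe$chrom, universe$start, universe$end)

  # randomised role assignment over the universe
  m <- nrow(universe)
  idx <- sample.int(m)
  n_core <- spec$n_core_regions
  n_var <- spec$n_variable_regions
  core_idx <- idx[seq_len(n_core)]
  var_idx <- if (n_var > 0) idx[n_core + seq_len(n_var)] else integer()
  spec_idx <- idx[setdiff(seq_len(m), seq_len(n_core + n_var))]

  universe$role <- NA_character_
  universe$role[core_idx] <- "core"
  universe$role[var_idx] <- "variable"
  universe$role[spec_idx] <- "sample_specific"
  universe$owner_sample <- NA_character_
  if (length(spec_idx) > 0) {
    owners <- rep(sample_id_strings(spec$n_samples),
                  each = spec$n_sample_specific_regions_per_sample)
    universe$owner_sample[spec_idx] <- owners
  }

  # planted regions are disjoint subsets of the core
  core_shuffled <- sample(core_idx)
  sig_idx <- head(core_shuffled, spec$n_signature_regions)
  dv_idx <- head(setdiff(core_shuffled, sig_idx), spec$n_diffvar_regions)
  universe$higher_in <- NA_character_
  if (length(sig_idx) > 0) {
    half <- ceiling(length(sig_idx) / 2)
    universe$higher_in[sig_idx[seq_len(half)]] <- "mutated"
    universe$higher_in[sig_idx[-seq_len(half)]] <- "unmutated"
  }
  universe$higher_var_in <- NA_character_
  if (length(dv_idx) > 0) {
    half <- ceiling(length(dv_idx) / 2)
    universe$higher_var_in[dv_idx[seq_len(half)]] <- "mutated"
    universe$higher_var_in[dv_idx[-seq_len(half)]] <- "unmutated"
  }
  universe
}

sample_id_strings <- function(n) sprintf("S%03d", seq_len(n))
patient_id_strings <- function(n) sprintf("P%03d", seq_len(n))

# ---- samples, patients, subtypes ------------------------------------------

build_sample_design <- function(spec) {
  sample_id <- sample_id_strings(spec$n_samples)
  patients <- patient_id_strings(spec$n_patients)
  assignment <- c(patients,
                  if (spec$n_samples > spec$n_patients)
                    sample(patients, spec$n_samples - spec$n_patients, replace = TRUE))

  n_int <- round(spec$intermediate_fraction * spec$n_patients)
  n_rest <- spec$n_patients - n_int
  n_mut <- round(spec$subtype_fraction_mutated * n_rest)
  if (n_mut < 1 || n_rest - n_mut < 1) {
    abort("subtype_fraction_mutated leaves fewer than one patient in a subtype")
  }
  subtype <- sample(c(rep("mutated", n_mut), rep("unmutated", n_rest - n_mut),
                      rep("intermediate", n_int)))
  names(subtype) <- patients

  homology <- vapply(subtype, function(s) {
    switch(s,
      mutated = runif(1, 88, 97.9),
      unmutated = runif(1, 98.2, 100),
      intermediate = runif(1, 97.6, 98.4)
    )
  }, numeric(1))

  labels <- tibble(
    sample_id = sample_id,
    patient_id = assignment,
    subtype = unname(subtype[assignment]),
    ighv_homology = round(unname(homology[assignment]), 1)
  )
  list(labels = labels)
}

# ---- count model -----------------------------------------------------------

build_count_params <- function(spec, universe, labels) {
  m <- nrow(universe)
  n <- nrow(labels)
  mu <- matrix(spec$background_mean, m, n)
  phi <- matrix(spec$dispersion, m, n)

  # per-region accessible-state baseline: mean-preserving lognormal spread
  # shared by all samples, as in real regulatory landscapes
  baseline <- spec$baseline_mean *
    exp(stats::rnorm(m, 0, spec$baseline_log_sd) - spec$baseline_log_sd^2 / 2)

  # presence: which regions are called accessible in which sample
  present <- matrix(FALSE, m, n)
  present[universe$role == "core", ] <- TRUE
  var_rows <- which(universe$role == "variable")
  if (length(var_rows) > 0) {
    pres <- matrix(runif(length(var_rows) * n) < spec$variable_presence_prob,
                   length(var_rows), n)
    owner <- sample.int(n, length(var_rows), replace = TRUE)
    pres[cbind(seq_along(var_rows), owner)] <- TRUE
    present[var_rows, ] <- pres
  }
  sp_rows <- which(universe$role == "sample_specific")
  if (length(sp_rows) > 0) {
    col <- match(universe$owner_sample[sp_rows], labels$sample_id)
    present[cbind(sp_rows, col)] <- TRUE
  }
  mu[present] <- matrix(baseline, m, n)[present]

  is_mut <- labels$subtype == "mutated"
  is_unm <- labels$subtype == "unmutated"
  is_int <- labels$subtype == "intermediate"

  # signature regions: symmetric log2 shift around the region baseline; the
  # expected group log2 ratio equals signature_log2_effect; intermediates
  # sit at the arithmetic midpoint of the two subtype means
  up_f <- 2^(spec$signature_log2_effect / 2)
  dn_f <- 2^(-spec$signature_log2_effect / 2)
  mid_f <- (up_f + dn_f) / 2
  sig_m <- which(universe$higher_in == "mutated")
  sig_u <- which(universe$higher_in == "unmutated")
  mu[sig_m, is_mut] <- baseline[sig_m] * up_f
  mu[sig_m, is_unm] <- baseline[sig_m] * dn_f
  mu[sig_m, is_int] <- baseline[sig_m] * mid_f
  mu[sig_u, is_mut] <- baseline[sig_u] * dn_f
  mu[sig_u, is_unm] <- baseline[sig_u] * up_f
  mu[sig_u, is_int] <- baseline[sig_u] * mid_f

  # diff-var regions: dispersion of the higher-variance group scaled so the
  # variance ratio is achieved at an unchanged mean:
  # var = mu + phi mu^2; phi' = r phi + (r - 1) / mu
  r <- spec$diffvar_variance_ratio
  phi_hi <- r * spec$dispersion + (r - 1) / baseline
  dv_m <- which(universe$higher_var_in == "mutated")
  dv_u <- which(universe$higher_var_in == "unmutated")
  phi[dv_m, is_mut] <- matrix(phi_hi, m, n)[dv_m, is_mut]
  phi[dv_u, is_unm] <- matrix(phi_hi, m, n)[dv_u, is_unm]

  list(mu = mu, size = 1 / phi, present = present)
}

draw_counts <- function(mu, size) {
  matrix(as.integer(rnbinom(length(mu), mu = as.vector(mu), size = as.vector(size))),
         nrow = nrow(mu))
}

# ---- emitted artefacts -----------------------------------------------------

build_peak_sets <- function(universe, present, sample_ids) {
  idx <- which(present, arr.ind = TRUE)
  tibble(
    sample_id = sample_ids[idx[, 2]],
    chrom = universe$chrom[idx[, 1]],
    start = universe$start[idx[, 1]],
    end = universe$end[idx[, 1]]
  ) |>
    arrange(sample_id, chrom, start)
}

build_fragments <- function(spec, universe, counts) {
  idx <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[idx]
  row <- rep(idx[, 1], reps)
  col <- rep(idx[, 2], reps)
  span <- spec$region_length - spec$fragment_length
  offs <- floor(runif(length(row), 0, span + 1))
  start <- universe$start[row] + as.integer(offs)
  tibble(
    sample_id = colnames(counts)[col],
    chrom = universe$chrom[row],
    start = start,
    end = start + spec$fragment_length
  ) |>
    arrange(sample_id, chrom, start)
}

build_gene_models <- function(spec, universe) {
  eligible <- which(universe$role %in% c("core", "variable"))
  n_anchored <- round(0.8 * spec$n_genes)
  n_free <- spec$n_genes - n_anchored
  candidates <- sample(eligible)
  body_len <- spec$gene_body_length

  accepted <- list()
  taken <- tibble(chrom = character(), lo = numeric(), hi = numeric())
  add_gene <- function(chrom, tss, anchor_region) {
    strand <- sample(c("+", "-"), 1)
    if (strand == "+") {
      body_start <- tss; body_end <- tss + body_len
    } else {
      body_start <- tss - body_len + 1; body_end <- tss + 1
    }
    if (body_start < 0 || body_end > spec$genome[chrom]) return(FALSE)
    clash <- taken |> filter(chrom == !!chrom, lo < body_end, hi > body_start)
    if (nrow(clash) > 0) return(FALSE)
    taken <<- bind_rows(taken, tibble(chrom = chrom, lo = body_start, hi = body_end))
    accepted[[length(accepted) + 1]] <<- tibble(
      chrom = chrom, strand = strand, tss = as.integer(tss),
      body_start = as.integer(body_start), body_end = as.integer(body_end),
      anchor_region = anchor_region
    )
    TRUE
  }

  got <- 0
  for (i in candidates) {
    if (got >= n_anchored) break
    tss <- floor(interval_midpoint(universe$start[i], universe$end[i]))
    if (add_gene(universe$chrom[i], tss, universe$region_id[i])) got <- got + 1
  }
  got_free <- 0
  for (i in sample(eligible)) {
    if (got_free >= n_free) break
    # place the TSS in the gap between regions, away from any region midpoint
    gap_tss <- universe$end[i] + floor(0.5 * (universe$end[i] - universe$start[i])) + 2500
    if (add_gene(universe$chrom[i], gap_tss, NA_character_)) got_free <- got_free + 1
  }
  genes <- bind_rows(accepted) |>
    arrange(chrom, tss) |>
    mutate(gene_id = sprintf("G%03d", row_number())) |>
    select(gene_id, chrom, strand, tss, body_start = "body_start",
           body_end = "body_end", anchor_region = "anchor_region")
  genes
}

build_footprints <- function(spec, universe, gene_models) {
  fs <- spec$footprint_spec
  anchored <- gene_models |> filter(!is.na(.data$anchor_region))
  peak_regions <- universe |> filter(role %in% c("core", "variable"))
  # nearest gene of every candidate region, so background sites can avoid
  # the neighbourhoods of planted targets and decoys
  region_gene <- annotate_nearest_tss(peak_regions, gene_models)
  nearest_gene <- setNames(region_gene$gene_id, region_gene$region_id)

  site_in_region <- function(region_row, n) {
    lo <- region_row$start
    hi <- region_row$end - 10L
    start <- lo + floor(runif(n, 0, max(hi - lo, 1) + 1))
    tibble(chrom = region_row$chrom, start = as.integer(start),
           end = as.integer(start + 10L))
  }
  draw_purity <- function(n, shape = fs$purity_shape) {
    0.5 + 0.5 * rbeta(n, shape[1], shape[2])
  }

  tfs <- sprintf("TF%02d", seq_len(fs$n_tfs))
  decoy_tfs <- if (fs$n_decoy_tfs > 0) sprintf("DTF%02d", seq_len(fs$n_decoy_tfs)) else character()

  planted <- list(); decoys <- list(); sites <- list()
  for (t in tfs) {
    targets <- anchored[sample.int(nrow(anchored), fs$n_targets_per_tf), ]
    remaining <- anchored |> filter(!gene_id %in% targets$gene_id)
    decoy_genes <- remaining[sample.int(nrow(remaining), fs$n_decoy_genes_per_tf), ]
    planted[[t]] <- tibble(tf = t, gene_id = targets$gene_id)
    decoys[[t]] <- tibble(tf = t, gene_id = decoy_genes$gene_id)

    # proximal high-purity sites inside each target gene's promoter region
    prox <- map_dfr(seq_len(nrow(targets)), function(k) {
      reg <- universe[universe$region_id == targets$anchor_region[k], ]
      site_in_region(reg, fs$n_proximal_sites) |>
        mutate(purity = draw_purity(fs$n_proximal_sites, c(10, 1.5)))
    })
    # one weak but qualifying site at each decoy gene's promoter region
    dec <- map_dfr(seq_len(nrow(decoy_genes)), function(k) {
      reg <- universe[universe$region_id == decoy_genes$anchor_region[k], ]
      site_in_region(reg, 1L) |>
        mutate(purity = runif(1, 0.705, 0.74))
    })
    # background sites in peak regions whose promoter gene (if any) is not a
    # planted target or decoy of this TF
    avoid_genes <- c(targets$gene_id, decoy_genes$gene_id)
    bg_pool <- peak_regions |>
      filter(!nearest_gene[region_id] %in% avoid_genes)
    n_total <- floor(runif(1, fs$sites_per_tf[1], fs$sites_per_tf[2] + 1))
    n_bg <- max(n_total - nrow(prox) - nrow(dec), 0)
    bg_rows <- bg_pool[sample.int(nrow(bg_pool), n_bg, replace = TRUE), ]
    bg <- site_in_region_vec(bg_rows) |> mutate(purity = draw_purity(n_bg))
    # low-purity sites (fail the purity filter) and off-peak sites (fail the
    # peak-overlap filter) exercise the filtering stage
    lowp_rows <- bg_pool[sample.int(nrow(bg_pool), 40, replace = TRUE), ]
    lowp <- site_in_region_vec(lowp_rows) |>
      mutate(purity = 0.5 + 0.2 * rbeta(40, 2, 4))
    offp <- tibble(
      chrom = names(spec$genome)[1],
      start = as.integer(seq(10, 200, length.out = 15)),
      end = as.integer(seq(10, 200, length.out = 15)) + 10L,
      purity = draw_purity(15)
    )
    sites[[t]] <- bind_rows(prox, dec, bg, lowp, offp) |> mutate(tf = t)
  }
  # decoy TFs carry a quarter of a retained TF's sites, so they fall below
  # any site-count filter calibrated to the retained TFs
  n_decoy_sites <- max(5L, floor(0.25 * fs$sites_per_tf[1]))
  for (t in decoy_tfs) {
    rows <- peak_regions[sample.int(nrow(peak_regions), n_decoy_sites, replace = TRUE), ]
    sites[[t]] <- site_in_region_vec(rows) |>
      mutate(purity = 0.5 + 0.5 * rbeta(n_decoy_sites, fs$purity_shape[1], fs$purity_shape[2]),
             tf = t)
  }
  list(
    sites = bind_rows(sites) |>
      select(tf, chrom, start, end, purity) |>
      arrange(tf, chrom, start),
    planted_edges = bind_rows(planted),
    decoy_edges = bind_rows(decoys)
  )
}

# vectorised placement of one 10-bp site inside each supplied region
site_in_region_vec <- function(region_rows) {
  n <- nrow(region_rows)
  lo <- region_rows$start
  hi <- region_rows$end - 10L
  start <- lo + floor(runif(n, 0, pmax(hi - lo, 1) + 1))
  tibble(chrom = region_rows$chrom, start = as.integer(start),
         end = as.integer(start + 10L))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d samples / %d patients; %d regions in the universe\n",
              ncol(x$counts), length(unique(x$sample_sheet$patient_id)), nrow(x$counts)))
  cat(sprintf("  %d fragments; %d footprint sites for %d TFs; %d genes\n",
              nrow(x$fragments), nrow(x$footprints),
              length(unique(x$footprints$tf)), nrow(x$gene_models)))
  invisible(x)
}

#' Assemble the accessibility matrix a synthetic cohort was drawn from
#'
#' Returns the cohort's drawn count matrix as an [accessibility
#' matrix][quantify_regions] (raw layer plus per-sample totals), bypassing
#' fragment counting. Counting the cohort's fragments over its region
#' universe with [quantify_regions()] yields the identical matrix.
#'
#' @param cohort A `synthetic_cohort`.
#' @return An `accessibility_matrix` with the raw layer filled in.
#' @export
cohort_matrix <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort")) abort("cohort must be a synthetic_cohort")
  new_accessibility_matrix(cohort$counts, totals = cohort$totals)
}
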