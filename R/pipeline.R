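#' Configure a pipeline run
#'
#' Collects every stage threshold, the input/output locations and the seed
#' into one validated configuration. Unknown fields are rejected; every
#' threshold is serialised into the run summary so any artefact can be
#' reproduced from the summary alone.
#'
#' @param out_dir Output directory for all stage artefacts.
#' @param seed Integer seed governing every source of randomness.
#' @param cohort A [cohort_spec()] used by the `simulate` stage (its seed
#'   is overridden by `seed`).
#' @param support_constitutive,support_rare Support-class boundaries.
#' @param homology_threshold IGHV homology threshold (percent).
#' @param alpha Significance level for differential variability.
#' @param mean_cutoff Mean-accessibility cutoff for differential
#'   variability.
#' @param importance_threshold Gini-importance threshold for signature
#'   extraction.
#' @param tf_min_sites,tf_purity_min TF footprint filter thresholds.
#' @param edge_threshold Network edge-score threshold.
#' @param k_clusters Clusters for the sample-clustering stage.
#' @param n_permutations Shuffled-label repetitions in the classify stage.
#' @param n_saturation_iterations Random orderings for the saturation
#'   analysis.
#' @param n_corridor_loci,corridor_pad Corridor stage: number of
#'   highest-support consensus regions to track and padding (bp).
#' @param rf Classifier configuration from [rf_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       cohort = cohort_spec(),
                       support_constitutive = 0.95,
                       support_rare = 0.05,
                       homology_threshold = 98,
                       alpha = 0.05,
                       mean_cutoff = 1,
                       importance_threshold = 1e-4,
                       tf_min_sites = 500,
                       tf_purity_min = 0.7,
                       edge_threshold = 1,
                       k_clusters = 4,
                       n_permutations = 100,
                       n_saturation_iterations = 100,
                       n_corridor_loci = 3,
                       corridor_pad = 500,
                       rf = rf_config()) {
  config <- list(
    out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
    support_constitutive = support_constitutive, support_rare = support_rare,
    homology_threshold = homology_threshold, alpha = alpha,
    mean_cutoff = mean_cutoff, importance_threshold = importance_threshold,
    tf_min_sites = tf_min_sites, tf_purity_min = tf_purity_min,
    edge_threshold = edge_threshold, k_clusters = k_clusters,
    n_permutations = n_permutations,
    n_saturation_iterations = n_saturation_iterations,
    n_corridor_loci = n_corridor_loci, corridor_pad = corridor_pad,
    rf = rf
  )
  validate_run_config(config)
  structure(config, class = "run_config")
}

validate_run_config <- function(config) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(inherits(config$cohort, "cohort_spec"), "cohort: must be a cohort_spec")
  chk(config$alpha > 0 && config$alpha < 1, "alpha: must be in (0, 1)")
  chk(config$mean_cutoff >= 0, "mean_cutoff: must be >= 0")
  chk(config$support_rare >= 0 && config$support_rare < config$support_constitutive &&
        config$support_constitutive <= 1,
      "support boundaries: need 0 <= support_rare < support_constitutive <= 1")
  chk(config$homology_threshold > 0 && config$homology_threshold < 100,
      "homology_threshold: must be in (0, 100)")
  chk(config$importance_threshold >= 0, "importance_threshold: must be >= 0")
  chk(config$tf_min_sites >= 1, "tf_min_sites: must be >= 1")
  chk(config$tf_purity_min > 0 && config$tf_purity_min < 1,
      "tf_purity_min: must be in (0, 1)")
  chk(config$edge_threshold >= 0, "edge_threshold: must be >= 0")
  chk(config$k_clusters >= 2, "k_clusters: must be >= 2")
  chk(config$n_permutations >= 1, "n_permutations: must be >= 1")
  chk(config$n_saturation_iterations >= 1, "n_saturation_iterations: must be >= 1")
  if (length(problems) > 0) {
    abort(paste0("invalid run configuration:\n", paste("-", problems, collapse = "\n")))
  }
  invisible(config)
}

pipeline_stages <- function() {
  c("simulate", "consensus", "matrix", "corridor", "variability",
    "classify", "cluster", "grn", "report")
}

#' Run one pipeline stage
#'
#' Executes a named stage against the configuration, writing its artefacts
#' under `out_dir/<stage>/` and appending timings, QC counters and input
#' checksums to `out_dir/run_summary.json`. Output files are written
#' atomically (temp file + rename). Missing inputs raise an error naming
#' the expected file.
#'
#' @param config A [run_config()].
#' @param stage One of `simulate`, `consensus`, `matrix`, `corridor`,
#'   `variability`, `classify`, `cluster`, `grn`, `report`.
#' @return Invisibly, a tibble listing the stage's artefacts.
#' @export
run_stage <- function(config, stage) {
  if (!inherits(config, "run_config")) abort("config must be a run_config")
  validate_run_config(config)
  stage <- match.arg(stage, pipeline_stages())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  result <- switch(stage,
    simulate = stage_simulate(config),
    consensus = stage_consensus(config),
    matrix = stage_matrix(config),
    corridor = stage_corridor(config),
    variability = stage_variability(config),
    classify = stage_classify(config),
    cluster = stage_cluster(config),
    grn = stage_grn(config),
    report = stage_report(config)
  )
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  update_run_summary(config, stage, result, elapsed)
  invisible(result$artifacts)
}

#' Run the full pipeline
#'
#' Runs the stages in dependency order, stopping at the first failure.
#'
#' @param config A [run_config()].
#' @param stages Stages to run (default: all, in order).
#' @param dry_run If `TRUE`, print the stage plan and write nothing.
#' @return Invisibly, the vector of completed stages.
#' @export
run_pipeline <- function(config, stages = pipeline_stages(), dry_run = FALSE) {
  if (!inherits(config, "run_config")) abort("config must be a run_config")
  validate_run_config(config)
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  if (dry_run) {
    cat("pipeline plan (no files will be written):\n")
    for (s in stages) cat(sprintf("  %s -> %s\n", s, file.path(config$out_dir, s)))
    return(invisible(character()))
  }
  done <- character()
  for (s in stages) {
    run_stage(config, s)
    done <- c(done, s)
  }
  invisible(done)
}

# ---- stage plumbing --------------------------------------------------------

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

require_input <- function(path, produced_by) {
  if (!file.exists(path)) {
    abort(sprintf("missing input %s (run the '%s' stage first)", path, produced_by))
  }
  path
}

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  if (!file.rename(tmp, path)) abort(sprintf("failed to write %s", path))
  path
}

write_matrix_tsv <- function(x, path) {
  atomic_write(path, function(p) {
    write_tsv_quiet(as_tibble(x, rownames = "region_id"), p)
  })
}

read_matrix_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}

update_run_summary <- function(config, stage, result, elapsed) {
  path <- file.path(config$out_dir, "run_summary.json")
  summary <- if (file.exists(path)) jsonlite::read_json(path) else list(
    package_version = as.character(packageVersion("atacohort")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = serialise_config(config),
    stages = list()
  )
  checks <- result$inputs %||% character()
  summary$stages[[stage]] <- list(
    elapsed_seconds = round(elapsed, 3),
    artifacts = result$artifacts$file,
    input_checksums = if (length(checks) > 0)
      as.list(tools::md5sum(checks)) else list(),
    qc = result$qc %||% list()
  )
  atomic_write(path, function(p) {
    jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
}

serialise_config <- function(config) {
  cfg <- unclass(config)
  cfg$cohort <- unclass(cfg$cohort)
  cfg$cohort$genome <- as.list(cfg$cohort$genome)
  cfg$rf <- unclass(cfg$rf)
  cfg
}

artifact_row <- function(...) tibble(file = c(...))

# ---- stages ----------------------------------------------------------------

stage_simulate <- function(config) {
  spec <- config$cohort
  spec$seed <- config$seed
  cohort <- generate_cohort(spec)
  d <- stage_dir(config, "simulate")
  manifest <- write_cohort(cohort, d)
  list(artifacts = manifest |> select(file), inputs = character(),
       qc = list(n_samples = nrow(cohort$sample_sheet),
                 n_fragments = nrow(cohort$fragments)))
}

read_sample_beds <- function(dir, suffix) {
  files <- sort(list.files(dir, pattern = paste0("\\.", suffix, "\\.bed$"),
                           full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no *.%s.bed files found in %s", suffix, dir))
  map_dfr(files, function(f) {
    sample <- sub(paste0("\\.", suffix, "\\.bed$"), "", basename(f))
    read_bed(f) |> mutate(sample_id = sample, .before = 1)
  })
}

stage_consensus <- function(config) {
  sim <- file.path(config$out_dir, "simulate")
  require_input(file.path(sim, "peaks"), "simulate")
  peaks <- read_sample_beds(file.path(sim, "peaks"), "peaks")
  consensus <- merge_peak_sets(peaks)
  supported <- region_support(consensus, peaks,
                              constitutive = config$support_constitutive,
                              rare = config$support_rare)
  sat <- saturation_curve(peaks, n_iterations = config$n_saturation_iterations,
                          seed = config$seed)
  d <- stage_dir(config, "consensus")
  f1 <- atomic_write(file.path(d, "consensus.bed"), function(p) {
    write_bed(consensus |> select(chrom, start, end, region_id), p)
  })
  f2 <- atomic_write(file.path(d, "support.tsv"), function(p) {
    write_tsv_quiet(as_tibble(supported), p)
  })
  f3 <- atomic_write(file.path(d, "saturation.tsv"), function(p) {
    write_tsv_quiet(as_tibble(sat), p)
  })
  class_counts <- table(supported$support_class)
  list(artifacts = artifact_row(f1, f2, f3),
       inputs = list.files(file.path(sim, "peaks"), full.names = TRUE),
       qc = list(n_regions = nrow(consensus),
                 support_classes = as.list(class_counts)))
}

read_consensus_artifact <- function(config) {
  path <- require_input(file.path(config$out_dir, "consensus", "consensus.bed"), "consensus")
  read_bed(path, extra_names = "region_id")
}

stage_matrix <- function(config) {
  sim <- file.path(config$out_dir, "simulate")
  consensus <- read_consensus_artifact(config)
  fragments <- read_sample_beds(require_input(file.path(sim, "fragments"), "simulate"),
                                "fragments")
  acc <- quantify_regions(consensus, fragments)
  acc <- quantile_normalize(acc)
  d <- stage_dir(config, "matrix")
  f1 <- write_matrix_tsv(acc$raw, file.path(d, "matrix_raw.tsv"))
  f2 <- write_matrix_tsv(acc$normalized, file.path(d, "matrix_normalized.tsv"))
  f3 <- atomic_write(file.path(d, "totals.tsv"), function(p) {
    write_tsv_quiet(tibble(sample_id = names(acc$totals),
                           total_filtered_reads = unname(acc$totals)), p)
  })
  list(artifacts = artifact_row(f1, f2, f3),
       inputs = file.path(config$out_dir, "consensus", "consensus.bed"),
       qc = acc$qc)
}

read_matrix_artifact <- function(config) {
  raw <- read_matrix_tsv(require_input(
    file.path(config$out_dir, "matrix", "matrix_raw.tsv"), "matrix"))
  norm <- read_matrix_tsv(require_input(
    file.path(config$out_dir, "matrix", "matrix_normalized.tsv"), "matrix"))
  totals_tbl <- utils::read.table(require_input(
    file.path(config$out_dir, "matrix", "totals.tsv"), "matrix"),
    sep = "\t", header = TRUE)
  acc <- new_accessibility_matrix(
    raw, totals = setNames(totals_tbl$total_filtered_reads, totals_tbl$sample_id))
  acc$normalized <- norm
  acc
}

stage_corridor <- function(config) {
  sim <- file.path(config$out_dir, "simulate")
  support <- utils::read.table(require_input(
    file.path(config$out_dir, "consensus", "support.tsv"), "consensus"),
    sep = "\t", header = TRUE)
  fragments <- read_sample_beds(require_input(file.path(sim, "fragments"), "simulate"),
                                "fragments")
  totals <- fragments |> count(sample_id, name = "total")
  loci <- as_tibble(support) |>
    arrange(desc(support), region_id) |>
    head(config$n_corridor_loci) |>
    transmute(chrom, start = pmax(start - config$corridor_pad, 0),
              end = end + config$corridor_pad)
  cov <- fragment_coverage(fragments, loci) |>
    left_join(totals, by = "sample_id") |>
    mutate(normalized = .data$coverage / .data$total * 1e7)
  corridor <- corridor_tracks(cov, value_col = "normalized")
  d <- stage_dir(config, "corridor")
  f1 <- atomic_write(file.path(d, "corridor.tsv"), function(p) {
    write_tsv_quiet(as_tibble(corridor), p)
  })
  paths <- write_corridor_bedgraphs(corridor, file.path(d, "corridor"))
  list(artifacts = artifact_row(f1, paths),
       inputs = file.path(config$out_dir, "consensus", "support.tsv"),
       qc = list(n_loci = nrow(loci), n_positions = nrow(corridor)))
}

read_sheet_artifact <- function(config) {
  read_sample_sheet(require_input(
    file.path(config$out_dir, "simulate", "sample_sheet.csv"), "simulate"))
}

stage_variability <- function(config) {
  acc <- read_matrix_artifact(config)
  sheet <- read_sheet_artifact(config)
  labels <- ighv_labels(sheet, threshold = config$homology_threshold)
  metrics <- variability_metrics(acc)
  dv <- differential_variability(acc, labels, alpha = config$alpha,
                                 mean_cutoff = config$mean_cutoff)
  d <- stage_dir(config, "variability")
  f1 <- atomic_write(file.path(d, "variability.tsv"), function(p) {
    write_tsv_quiet(metrics, p)
  })
  f2 <- atomic_write(file.path(d, "diffvar.tsv"), function(p) {
    write_tsv_quiet(as_tibble(dv), p)
  })
  list(artifacts = artifact_row(f1, f2),
       inputs = file.path(config$out_dir, "matrix", "matrix_normalized.tsv"),
       qc = as.list(glance(dv)))
}

stage_classify <- function(config) {
  acc <- read_matrix_artifact(config)
  sheet <- read_sheet_artifact(config)
  labels <- ighv_labels(sheet, threshold = config$homology_threshold)
  patients <- sheet |> select(sample_id, patient_id)
  fit <- patient_aware_loocv(acc, labels, patients, model_config = config$rf,
                             seed = config$seed)
  null_dist <- shuffled_label_null(acc, labels, patients,
                                   n_permutations = config$n_permutations,
                                   seed = config$seed, model_config = config$rf)
  signature <- extract_signature(fit, acc, labels,
                                 importance_threshold = config$importance_threshold)
  d <- stage_dir(config, "classify")
  f1 <- atomic_write(file.path(d, "scores.tsv"), function(p) write_tsv_quiet(fit$scores, p))
  f2 <- atomic_write(file.path(d, "roc.tsv"), function(p) write_tsv_quiet(fit$roc, p))
  f3 <- atomic_write(file.path(d, "importance.tsv"), function(p) write_tsv_quiet(fit$importance, p))
  f4 <- atomic_write(file.path(d, "signature.tsv"), function(p) write_tsv_quiet(as_tibble(signature), p))
  f5 <- atomic_write(file.path(d, "null_auc.tsv"), function(p) write_tsv_quiet(as_tibble(null_dist), p))
  list(artifacts = artifact_row(f1, f2, f3, f4, f5),
       inputs = file.path(config$out_dir, "matrix", "matrix_normalized.tsv"),
       qc = list(auc = fit$auc, n_signature = nrow(signature),
                 null_mean_auc = mean(null_dist$auc),
                 n_failed_permutations = length(attr(null_dist, "failures"))))
}

stage_cluster <- function(config) {
  acc <- read_matrix_artifact(config)
  sig <- utils::read.table(require_input(
    file.path(config$out_dir, "classify", "signature.tsv"), "classify"),
    sep = "\t", header = TRUE)
  regions <- if (nrow(sig) >= 2) sig$region_id else NULL
  clusters <- cluster_samples(acc, regions = regions, k = config$k_clusters)
  pca <- pca_projection(acc, n_components = 2)
  d <- stage_dir(config, "cluster")
  f1 <- atomic_write(file.path(d, "clusters.tsv"), function(p) {
    write_tsv_quiet(as_tibble(clusters), p)
  })
  f2 <- atomic_write(file.path(d, "pca.tsv"), function(p) {
    write_tsv_quiet(as_tibble(pca), p)
  })
  list(artifacts = artifact_row(f1, f2),
       inputs = file.path(config$out_dir, "classify", "signature.tsv"),
       qc = list(cluster_sizes = as.list(table(clusters$cluster)),
                 explained_variance = attr(pca, "explained_variance")))
}

stage_grn <- function(config) {
  sim <- file.path(config$out_dir, "simulate")
  fp <- read_footprints(require_input(file.path(sim, "footprints.tsv"), "simulate"))
  genes <- read_gene_models(require_input(file.path(sim, "genes.bed"), "simulate"))
  consensus <- read_consensus_artifact(config)
  filtered <- filter_tfs(fp, consensus, min_sites = config$tf_min_sites,
                         purity_min = config$tf_purity_min)
  assignments <- assign_sites_to_genes(filtered$sites, genes)
  scores <- interaction_scores(assignments)
  network <- build_network(scores, edge_threshold = config$edge_threshold)
  d <- stage_dir(config, "grn")
  f1 <- atomic_write(file.path(d, "network_edges.tsv"), function(p) {
    write_tsv_quiet(network$edges, p)
  })
  f2 <- atomic_write(file.path(d, "node_degrees.tsv"), function(p) {
    write_tsv_quiet(network$nodes, p)
  })
  f3 <- atomic_write(file.path(d, "tf_summary.tsv"), function(p) {
    write_tsv_quiet(filtered$summary, p)
  })
  list(artifacts = artifact_row(f1, f2, f3),
       inputs = file.path(sim, "footprints.tsv"),
       qc = list(n_retained_tfs = length(filtered$retained_tfs),
                 n_edges = network$n_edges))
}

stage_report <- function(config) {
  path <- require_input(file.path(config$out_dir, "run_summary.json"), "any earlier stage")
  summary <- jsonlite::read_json(path)
  d <- stage_dir(config, "report")
  f1 <- atomic_write(file.path(d, "report.json"), function(p) {
    jsonlite::write_json(list(
      completed_stages = names(summary$stages),
      total_elapsed_seconds = sum(vapply(summary$stages,
                                         function(s) s$elapsed_seconds, 1)),
      qc = map(summary$stages, "qc")
    ), p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  list(artifacts = artifact_row(f1), inputs = path, qc = list())
}
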