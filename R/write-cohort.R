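#' Write a synthetic cohort to disk
#'
#' Emits the cohort as the plain-text formats the analysis stages consume:
#' one peak BED and one fragment BED per sample (0-based, half-open), a
#' comma-separated sample sheet, a BED6 gene-model file, a tab-separated
#' footprint table and a JSON ground-truth manifest. A file manifest is
#' returned and also written as `manifest.tsv`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param directory Output directory (created if needed).
#' @return A tibble manifest with columns `file`, `type`, `n_records`.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) abort("cohort must be a synthetic_cohort")
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) abort(sprintf("cannot create output directory: %s", directory))
  dir.create(file.path(directory, "peaks"), showWarnings = FALSE)
  dir.create(file.path(directory, "fragments"), showWarnings = FALSE)

  manifest <- list()
  note <- function(file, type, n) {
    manifest[[length(manifest) + 1]] <<- tibble(file = file, type = type, n_records = n)
  }

  for (s in cohort$sample_sheet$sample_id) {
    pk <- cohort$peaks |> filter(sample_id == s) |> select(chrom, start, end)
    fr <- cohort$fragments |> filter(sample_id == s) |> select(chrom, start, end)
    pk_path <- file.path(directory, "peaks", paste0(s, ".peaks.bed"))
    fr_path <- file.path(directory, "fragments", paste0(s, ".fragments.bed"))
    write_bed(pk, pk_path); note(pk_path, "peaks", nrow(pk))
    write_bed(fr, fr_path); note(fr_path, "fragments", nrow(fr))
  }

  ss_path <- file.path(directory, "sample_sheet.csv")
  utils::write.table(cohort$sample_sheet, ss_path, sep = ",", quote = FALSE, row.names = FALSE)
  note(ss_path, "sample_sheet", nrow(cohort$sample_sheet))

  gm_path <- file.path(directory, "genes.bed")
  gm <- cohort$gene_models |>
    transmute(chrom, start = .data$body_start, end = .data$body_end,
              name = gene_id, score = 0L, strand)
  write_bed(gm, gm_path)
  note(gm_path, "gene_models", nrow(gm))

  fp_path <- file.path(directory, "footprints.tsv")
  fp <- cohort$footprints |> mutate(purity = round(purity, 6))
  utils::write.table(fp, fp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  note(fp_path, "footprints", nrow(fp))

  gt_path <- file.path(directory, "ground_truth.json")
  gt <- cohort$ground_truth
  jsonlite::write_json(list(
    labels = gt$labels,
    signature_regions = gt$signature_regions,
    diffvar_regions = gt$diffvar_regions,
    region_roles = gt$regions |> select(region_id, role, owner_sample = "owner_sample"),
    planted_edges = gt$planted_edges,
    decoy_edges = gt$decoy_edges,
    seed = cohort$spec$seed
  ), gt_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  note(gt_path, "ground_truth", nrow(gt$labels))

  manifest <- bind_rows(manifest)
  write_tsv_quiet(manifest, file.path(directory, "manifest.tsv"))
  manifest
}

#' Read gene models written by [write_cohort()]
#'
#' Reconstructs the TSS from the BED6 gene body and strand: for `+` genes the
#' TSS is the body start, for `-` genes the last base of the body.
#'
#' @param path Path to a BED6 gene-model file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `body_start`, `body_end`.
#' @export
read_gene_models <- function(path) {
  x <- read_bed(path, extra_names = c("gene_id", "score", "strand"))
  if (!all(c("gene_id", "strand") %in% names(x))) {
    abort(sprintf("gene model file %s must be BED6 (chrom, start, end, name, score, strand)", path))
  }
  x |>
    transmute(gene_id, chrom, strand,
              tss = ifelse(strand == "+", start, end - 1L),
              body_start = start, body_end = end)
}
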