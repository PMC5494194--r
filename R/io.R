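#' Read a BED file of genomic intervals
#'
#' Reads the first three (or four) columns of a BED file into a tibble with
#' 0-based, half-open coordinates, exactly as stored on disk. No coordinate
#' shifting is performed.
#'
#' @param path Path to a BED file (plain text, tab-separated, no header).
#' @param extra_names Optional names for columns beyond chrom/start/end.
#' @return A tibble with columns `chrom`, `start`, `end` and any extras.
#' @export
read_bed <- function(path, extra_names = NULL) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  base_names <- c("chrom", "start", "end")
  n_extra <- ncol(x) - 3L
  if (n_extra < 0) abort(sprintf("malformed BED file (fewer than 3 columns): %s", path))
  extra <- if (n_extra > 0) {
    if (!is.null(extra_names) && length(extra_names) >= n_extra) {
      extra_names[seq_len(n_extra)]
    } else {
      paste0("V", seq_len(n_extra) + 3L)
    }
  } else character()
  names(x) <- c(base_names, extra)
  x <- as_tibble(x)
  bad <- which(!(x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("malformed interval in %s at line %d: start >= end", path, bad[1]))
  }
  x
}

#' Write intervals to a BED file
#'
#' @param x A tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and optionally further columns, written in order after the first three.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, what = sprintf("BED output (%s)", path))
  ord <- c("chrom", "start", "end", setdiff(names(x), c("chrom", "start", "end")))
  ok <- try(utils::write.table(x[, ord], path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) abort(sprintf("failed to write BED file: %s", path))
  invisible(path)
}

#' Read a sample sheet
#'
#' Expects a delimited text file (comma- or tab-separated, with header) with
#' at least the columns `sample_id`, `patient_id` and `ighv_homology`
#' (percent germline homology of the IGHV gene, in `[80, 100]`, possibly
#' missing).
#'
#' @param path Path to the sample sheet.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("sample sheet not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  x <- as_tibble(utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE))
  need <- c("sample_id", "patient_id", "ighv_homology")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("sample sheet %s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$sample_id)) abort("sample sheet has duplicated sample_id values")
  x
}

#' Read a transcription-factor footprint table
#'
#' Delimited text (comma or tab, header row) with columns `tf`, `chrom`,
#' `start`, `end`, `purity`. Coordinates are 0-based, half-open; purity is
#' the footprint caller's confidence score in `(0, 1]`.
#'
#' @param path Path to the footprint table.
#' @return A tibble of footprint sites.
#' @export
read_footprints <- function(path) {
  if (!file.exists(path)) abort(sprintf("footprint table not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  x <- as_tibble(utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE))
  need <- c("tf", "chrom", "start", "end", "purity")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("footprint table %s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  check_intervals(x, what = sprintf("footprint table (%s)", path))
  if (any(x$purity <= 0 | x$purity > 1)) {
    abort(sprintf("footprint table %s has purity values outside (0, 1]", path))
  }
  x
}

#' Write a bedGraph track
#'
#' Consecutive positions with equal values are collapsed into intervals, the
#' standard run-length encoding of bedGraph.
#'
#' @param track A tibble with columns `chrom`, `pos` (0-based base position)
#'   and one value column named by `value_col`.
#' @param path Output path.
#' @param value_col Name of the value column to emit.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, value_col = "value") {
  if (!all(c("chrom", "pos", value_col) %in% names(track))) {
    abort("track must have columns chrom, pos and the requested value column")
  }
  out <- track |>
    group_by(chrom) |>
    arrange(pos, .by_group = TRUE) |>
    mutate(
      .brk = cumsum(c(1, diff(pos) != 1) | c(1, diff(.data[[value_col]]) != 0))
    ) |>
    group_by(chrom, .brk) |>
    summarise(
      start = min(pos), end = max(pos) + 1L,
      value = .data[[value_col]][1], .groups = "drop"
    ) |>
    select(chrom, start, end, value) |>
    arrange(chrom, start)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# delimited-table writers used by the pipeline stages
write_tsv_quiet <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
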