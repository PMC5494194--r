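# Internal helpers shared across modules.
#
# All user-facing interval tables use BED conventions: 0-based, half-open
# [start, end). GenomicRanges is 1-based and closed, so the two conversion
# helpers below are the only places where the +1/-0 arithmetic happens.

# validate an interval tibble with columns chrom/start/end
check_intervals <- function(x, what = "interval table", require_cols = c("chrom", "start", "end")) {
  if (!is.data.frame(x)) {
    abort(sprintf("%s must be a data frame", what))
  }
  missing_cols <- setdiff(require_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", what, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
      abort(sprintf("%s contains empty chromosome names", what))
    }
    bad <- which(!(x$start < x$end))
    if (length(bad) > 0) {
      abort(sprintf(
        "%s contains invalid interval(s) with start >= end (first at row %d: [%s, %s))",
        what, bad[1], format(x$start[bad[1]]), format(x$end[bad[1]])
      ))
    }
    if (any(x$start < 0)) {
      abort(sprintf("%s contains negative start coordinates", what))
    }
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed)
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> 0-based half-open tibble
as_bed_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# stable region identifier used throughout outputs
region_id_string <- function(chrom, start, end) {
  sprintf("%s_%d_%d", chrom, as.integer(start), as.integer(end))
}

# midpoint of a half-open interval (may be half-integer; kept numeric)
interval_midpoint <- function(start, end) {
  (start + end) / 2
}

# deterministic per-task seed streams derived from one master seed,
# kept below 2^31 for 32-bit R integers
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483399) + 1L
}

# validate a genome description; returns a named numeric vector of lengths
check_genome <- function(genome) {
  if (is.data.frame(genome)) {
    genome <- setNames(genome$length, genome$chrom)
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    abort("genome must be a named vector (chromosome -> length) or a tibble with columns chrom, length")
  }
  if (any(genome <= 0)) abort("chromosome lengths must be positive")
  genome
}
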