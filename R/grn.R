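#' Filter transcription-factor footprint sites
#'
#' A site qualifies when its purity score is strictly above `purity_min`
#' and it overlaps at least one accessible peak region by 1 bp or more. A
#' transcription factor is retained when it has at least `min_sites`
#' qualifying sites; only qualifying sites of retained TFs pass through.
#'
#' @param sites Footprint tibble (`tf`, `chrom`, `start`, `end`, `purity`).
#' @param peaks Interval tibble of accessible regions.
#' @param min_sites Minimum number of qualifying sites for a TF.
#' @param purity_min Purity threshold (strict).
#' @return A list with `sites` (qualifying sites of retained TFs),
#'   `retained_tfs` and a per-TF `summary` tibble.
#' @export
filter_tfs <- function(sites, peaks, min_sites = 500, purity_min = 0.7) {
  check_intervals(sites, "footprint table", c("tf", "chrom", "start", "end", "purity"))
  check_intervals(peaks, "peak table")
  if (nrow(peaks) == 0) abort("peak set is empty")
  in_peak <- IRanges::overlapsAny(as_granges0(sites), as_granges0(peaks))
  qual <- sites$purity > purity_min & in_peak
  summary <- sites |>
    mutate(qualifying = qual) |>
    group_by(tf) |>
    summarise(n_sites = n(), n_qualifying = sum(qualifying), .groups = "drop") |>
    mutate(retained = .data$n_qualifying >= min_sites)
  retained <- summary$tf[summary$retained]
  list(
    sites = sites[qual & sites$tf %in% retained, ],
    retained_tfs = retained,
    summary = summary
  )
}

#' Assign footprint sites to target genes
#'
#' A site located in a gene body, or within `upstream_bp` upstream of a
#' gene's TSS (strand-aware), is assigned to that gene — to all such genes
#' if several overlap. Any other (intergenic) site is assigned to the
#' single gene with the nearest TSS, measured from the site midpoint, with
#' ties broken towards the lexicographically smallest gene ID. The
#' distance `d` reported for every assignment is the absolute
#' midpoint-to-TSS distance. Sites on chromosomes without genes are left
#' unassigned and flagged.
#'
#' @param sites Footprint tibble (after [filter_tfs()]).
#' @param genes Gene model tibble (`gene_id`, `chrom`, `strand`, `tss`,
#'   `body_start`, `body_end`).
#' @param upstream_bp Width of the upstream promoter window.
#' @return A tibble with one row per (site, gene) assignment: `tf`,
#'   `chrom`, `start`, `end`, `purity`, `gene_id`, `distance`, `class`
#'   (body, upstream or intergenic_nearest). Unassigned sites appear with
#'   `gene_id = NA` and `class = "unassigned"`.
#' @export
assign_sites_to_genes <- function(sites, genes, upstream_bp = 2500) {
  check_intervals(sites, "footprint table", c("tf", "chrom", "start", "end", "purity"))
  need <- c("gene_id", "chrom", "strand", "tss", "body_start", "body_end")
  if (!all(need %in% names(genes))) {
    abort(sprintf("genes must have columns %s", paste(need, collapse = ", ")))
  }
  site_gr <- as_granges0(sites)
  mid <- interval_midpoint(sites$start, sites$end)

  body_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$body_start + 1L, genes$body_end))
  up_start <- ifelse(genes$strand == "+", genes$tss - upstream_bp, genes$tss + 1L)
  up_end <- ifelse(genes$strand == "+", genes$tss, genes$tss + upstream_bp + 1L)
  up_start <- pmax(up_start, 0)
  up_gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(up_start + 1L, up_end))

  body_hits <- GenomicRanges::findOverlaps(site_gr, body_gr)
  up_hits <- GenomicRanges::findOverlaps(site_gr, up_gr)
  direct <- bind_rows(
    tibble(site = S4Vectors::queryHits(body_hits),
           gene = S4Vectors::subjectHits(body_hits), class = "body"),
    tibble(site = S4Vectors::queryHits(up_hits),
           gene = S4Vectors::subjectHits(up_hits), class = "upstream")
  ) |>
    # a site both in a body and in an upstream window of the same gene is
    # reported once, as a body hit
    arrange(.data$site, .data$gene, .data$class) |>
    distinct(.data$site, .data$gene, .keep_all = TRUE)

  assigned <- direct |>
    transmute(site = .data$site, gene_id = genes$gene_id[.data$gene],
              class = .data$class,
              distance = abs(mid[.data$site] - genes$tss[.data$gene]))

  intergenic <- setdiff(seq_len(nrow(sites)), unique(direct$site))
  genes_sorted <- genes |> arrange(chrom, tss, gene_id)
  by_chrom <- split(genes_sorted, genes_sorted$chrom)
  nearest <- map_dfr(intergenic, function(i) {
    g <- by_chrom[[sites$chrom[i]]]
    if (is.null(g)) {
      return(tibble(site = i, gene_id = NA_character_,
                    class = "unassigned", distance = NA_real_))
    }
    d <- abs(g$tss - mid[i])
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(g$gene_id[best])][1]
    tibble(site = i, gene_id = g$gene_id[best],
           class = "intergenic_nearest", distance = d[best])
  })

  all_assign <- bind_rows(assigned, nearest) |> arrange(.data$site)
  bind_cols(
    sites[all_assign$site, c("tf", "chrom", "start", "end", "purity")],
    all_assign |> select(gene_id, distance, class)
  )
}

#' Transcription factor-to-gene interaction scores
#'
#' The interaction score between TF t and gene g sums a per-site weight
#' over all n sites of t assigned to g:
#' `S_t,g = sum_i  purity_scale * (P_i - purity_offset) * 10^(-d_i,g / decay_bp)`.
#' With the defaults the weight is 1 for a perfectly pure site at the TSS,
#' vanishes at the chance-level purity 0.5, and decays tenfold per megabase
#' of distance. The functional form and constants are recorded in the
#' returned attributes.
#'
#' @param assignments Output of [assign_sites_to_genes()] on filtered
#'   sites; unassigned rows are ignored.
#' @param purity_offset Purity value at which the weight vanishes.
#' @param purity_scale Multiplier of the purity term.
#' @param decay_bp Distance (bp) over which the weight decays tenfold.
#' @return A tibble with columns `tf`, `gene_id`, `n_sites`, `score`,
#'   sorted by decreasing score. Pairs without assigned sites are absent
#'   (score 0).
#' @export
interaction_scores <- function(assignments, purity_offset = 0.5,
                               purity_scale = 2, decay_bp = 1e6) {
  need <- c("tf", "gene_id", "purity", "distance")
  if (!all(need %in% names(assignments))) {
    abort(sprintf("assignments must have columns %s", paste(need, collapse = ", ")))
  }
  out <- assignments |>
    filter(!is.na(gene_id)) |>
    mutate(weight = purity_scale * (purity - purity_offset) * 10^(-distance / decay_bp)) |>
    group_by(tf, gene_id) |>
    summarise(n_sites = n(), score = sum(.data$weight), .groups = "drop") |>
    arrange(desc(score))
  structure(out,
            weight_form = "purity_scale * (P - purity_offset) * 10^(-d / decay_bp)",
            purity_offset = purity_offset, purity_scale = purity_scale,
            decay_bp = decay_bp)
}

#' Build a regulatory network from interaction scores
#'
#' Edges are exactly the TF-to-gene pairs whose interaction score is
#' strictly above the threshold; nodes without any edge are dropped.
#'
#' @param scores Output of [interaction_scores()].
#' @param edge_threshold Strict lower bound on the edge score.
#' @return An object of class `regulatory_network`: list with `edges`
#'   (tibble `tf`, `gene_id`, `score`), `nodes` (tibble `node`, `type`,
#'   `degree`) and `n_edges`.
#' @export
build_network <- function(scores, edge_threshold = 1) {
  if (!all(c("tf", "gene_id", "score") %in% names(scores))) {
    abort("scores must have columns tf, gene_id, score")
  }
  if (any(!is.finite(scores$score))) abort("scores must be finite")
  edges <- scores |>
    filter(score > edge_threshold) |>
    select(tf, gene_id, score)
  out_deg <- edges |> count(node = tf) |> mutate(type = "tf")
  in_deg <- edges |> count(node = gene_id) |> mutate(type = "gene")
  nodes <- bind_rows(out_deg, in_deg) |>
    group_by(.data$node) |>
    summarise(type = paste(sort(unique(type)), collapse = "+"),
              degree = sum(n), .groups = "drop")
  structure(list(edges = edges, nodes = nodes, n_edges = nrow(edges),
                 edge_threshold = edge_threshold),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d edges over %d nodes (threshold > %g)\n",
              x$n_edges, nrow(x$nodes), x$edge_threshold))
  invisible(x)
}

#' @describeIn build_network Edge list of the network.
#' @param x A `regulatory_network`.
#' @param ... Unused.
#' @export
tidy.regulatory_network <- function(x, ...) x$edges

#' @describeIn build_network One-row summary of network size.
#' @export
glance.regulatory_network <- function(x, ...) {
  tibble(
    n_edges = x$n_edges,
    n_nodes = nrow(x$nodes),
    n_tfs = sum(grepl("tf", x$nodes$type)),
    n_genes = sum(grepl("gene", x$nodes$type))
  )
}

#' Differential connectivity between two regulatory networks
#'
#' Each node's degree is divided by the total number of edges of its
#' network (compensating for differences in overall network size); the
#' change for nodes present in both networks is the log2 ratio of these
#' normalised degrees, ranked by absolute value. Nodes present in only one
#' network are reported separately with a direction flag.
#'
#' @param net_a,net_b `regulatory_network` objects to compare.
#' @param min_degree Optional reporting filter: keep shared nodes whose
#'   degree exceeds this value in at least one network. Applied only to the
#'   returned `shared` table's `reported` flag, never to the statistics.
#' @return A list of class `differential_connectivity` with `shared`
#'   (tibble `node`, `degree_a`, `degree_b`, `norm_a`, `norm_b`,
#'   `log2_change`, `rank`), and `exclusive` (nodes in only one network).
#' @export
differential_connectivity <- function(net_a, net_b, min_degree = 0) {
  if (!inherits(net_a, "regulatory_network") || !inherits(net_b, "regulatory_network")) {
    abort("net_a and net_b must be regulatory_network objects")
  }
  if (net_a$n_edges == 0 || net_b$n_edges == 0) {
    abort("both networks must have at least one edge")
  }
  a <- net_a$nodes |> select(node = "node", degree_a = "degree")
  b <- net_b$nodes |> select(node = "node", degree_b = "degree")
  shared <- inner_join(a, b, by = "node") |>
    mutate(
      norm_a = .data$degree_a / net_a$n_edges,
      norm_b = .data$degree_b / net_b$n_edges,
      log2_change = log2(.data$norm_a / .data$norm_b),
      reported = pmax(.data$degree_a, .data$degree_b) > min_degree
    ) |>
    arrange(desc(abs(.data$log2_change))) |>
    mutate(rank = row_number())
  exclusive <- bind_rows(
    anti_join(a, b, by = "node") |> mutate(present_in = "a"),
    anti_join(b, a, by = "node") |> mutate(present_in = "b")
  )
  structure(list(shared = shared, exclusive = exclusive),
            class = "differential_connectivity")
}

#' @describeIn differential_connectivity Shared-node table.
#' @param x A `differential_connectivity`.
#' @param ... Unused.
#' @export
tidy.differential_connectivity <- function(x, ...) x$shared
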