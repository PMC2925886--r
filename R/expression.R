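#' Rank genes by expression and call ON/OFF states
#'
#' Genes are ranked by expression value and assigned percentile ranks
#' (`100 * (rank - 1) / n`). In the default (quartile) mode, expressed
#' ("ON") genes are the top two quartiles of ranked genes and non-expressed
#' ("OFF") genes the bottom quartile; the remaining quartile is `neither`.
#' In whole-genome mode, ON is the top 25% and OFF the bottom 25%.
#'
#' Ties are broken by stable `gene_id` order; when tied values span a
#' quartile edge a message is emitted. A table where every value is equal
#' has no usable ranking and errors unless `force_stable = TRUE`.
#'
#' @param expression A data frame with columns `gene_id`, `value`.
#' @param whole_genome If `TRUE`, use the top-25%/bottom-25% rule.
#' @param force_stable Accept a fully tied table, ranking by gene_id.
#' @return A tibble (gene_id, value, percentile, status) with status in
#'   `ON`, `OFF`, `neither`.
#' @export
call_on_off <- function(expression, whole_genome = FALSE,
                        force_stable = FALSE) {
  e <- as_tibble(expression)
  if (!all(c("gene_id", "value") %in% names(e))) {
    abort("expression table needs columns gene_id and value")
  }
  if (nrow(e) < 4) abort("need at least 4 genes to form quartiles")
  if (n_distinct(e$value) == 1 && !force_stable) {
    abort("untiable ranking: all expression values are equal")
  }
  n <- nrow(e)
  ord <- order(e$value, e$gene_id)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  pct <- 100 * (rank - 1) / n

  lo <- if (whole_genome) 25 else 25
  hi <- if (whole_genome) 75 else 50
  # warn when ties straddle a status edge
  edges <- sort(unique(c(lo, hi)))
  for (edge in edges) {
    cut_val <- sort(e$value)[ceiling(edge / 100 * n)]
    straddle <- sum(e$value == cut_val) > 1 &&
      any(pct[e$value == cut_val] < edge) &&
      any(pct[e$value == cut_val] >= edge)
    if (isTRUE(straddle)) {
      inform(paste0("tied expression values span the ", edge,
                    "% edge; broken by gene_id order"))
    }
  }
  e %>%
    mutate(
      percentile = pct,
      status = case_when(
        pct >= hi ~ "ON",
        pct < lo ~ "OFF",
        TRUE ~ "neither"
      )
    )
}

#' Intersect ON/OFF calls from two platforms
#'
#' A gene keeps a status only when both platforms assign it the same
#' status; otherwise it becomes `neither`. Genes absent from either table
#' are dropped.
#'
#' @param table_a,table_b Tibbles from [call_on_off()].
#' @return A tibble (gene_id, status).
#' @export
intersect_calls <- function(table_a, table_b) {
  a <- as_tibble(table_a)[, c("gene_id", "status")]
  b <- as_tibble(table_b)[, c("gene_id", "status")]
  inner_join(a, b, by = "gene_id", suffix = c("_a", "_b")) %>%
    mutate(status = ifelse(.data$status_a == .data$status_b,
                           .data$status_a, "neither")) %>%
    select("gene_id", "status")
}

#' Gene expression scores from tiling-array expression channels
#'
#' For two-channel tiling-array expression data (cDNA vs genomic DNA), the
#' per-gene score is the mean of two components: the mean oligo-dT-primed
#' Z-score over tiles in the 3'-most `window` bases of the gene
#' (strand-aware; genes shorter than the window use all their tiles), and
#' the mean random-primed Z-score over all tiles in the gene. Genes with no
#' tiles in the oligo-dT window get a missing score.
#'
#' @param oligo_dt,random_primed Z-score `tile_track`s for the oligo-dT and
#'   random-primed expression channels.
#' @param tiles Tile table (tile_id, chrom, start, end).
#' @param models A `gene_models` object.
#' @param window 3' window size in bases (default 2000).
#' @return A tibble (gene_id, value) suitable for [call_on_off()].
#' @export
encode_array_expression <- function(oligo_dt, random_primed, tiles, models,
                                    window = 2000) {
  stopifnot(inherits(models, "gene_models"))
  tiles <- as_tibble(tiles)
  tiles$midpoint <- (tiles$start + tiles$end) %/% 2L
  od <- track_values(oligo_dt)
  rp <- track_values(random_primed)
  genes <- models$genes

  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    in_gene <- tiles$chrom == g$chrom &
      tiles$midpoint >= g$start & tiles$midpoint < g$end
    w <- min(window, g$span)
    if (g$strand == "+") {
      in_win <- in_gene & tiles$midpoint >= g$end - w
    } else {
      in_win <- in_gene & tiles$midpoint < g$start + w
    }
    od_vals <- od$value[match(tiles$tile_id[in_win], od$tile_id)]
    rp_vals <- rp$value[match(tiles$tile_id[in_gene], rp$tile_id)]
    score <- if (!any(in_win) || all(is.na(od_vals))) {
      NA_real_
    } else {
      mean(c(mean(od_vals, na.rm = TRUE), mean(rp_vals, na.rm = TRUE)))
    }
    tibble(gene_id = g$gene_id, value = score)
  })
}

#' Bin genes by expression percentile
#'
#' Genes are ranked, converted to percentile ranks, and assigned to
#' half-open percentile intervals `[lo, hi)` (the last bin is closed at
#' 100). The default 12-bin edges resolve the extremes (0-5, 5-10, 90-95,
#' 95-100) more finely than the deciles in between.
#'
#' @param expression A data frame with columns `gene_id`, `value`.
#' @param edges Strictly increasing percentile edges from 0 to 100.
#' @return A tibble (gene_id, value, percentile, bin, bin_label) where
#'   `bin` is the 1-based bin index.
#' @export
expression_bins <- function(expression,
                            edges = c(0, 5, 10, 20, 30, 40, 50, 60, 70,
                                      80, 90, 95, 100)) {
  e <- as_tibble(expression)
  if (is.unsorted(edges, strictly = TRUE)) {
    abort("bin edges must be strictly increasing")
  }
  if (edges[1] != 0 || edges[length(edges)] != 100) {
    abort("bin edges must run from 0 to 100")
  }
  n_bins <- length(edges) - 1
  if (nrow(e) < n_bins) abort("need at least as many genes as bins")
  n <- nrow(e)
  ord <- order(e$value, e$gene_id)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  pct <- 100 * (rank - 1) / n
  bin <- findInterval(pct, edges, rightmost.closed = TRUE)
  labels <- paste0(edges[-length(edges)], "-", edges[-1], "%")
  e %>%
    mutate(percentile = pct, bin = bin, bin_label = labels[bin])
}

#' Stratify alternative exons by inclusion level
#'
#' Partitions alternative exons into inclusion-level groups, by default
#' `[0, 0.5)` ("0-50% inclusion") and `[0.5, 1]` ("50-100% inclusion").
#' Intervals are half-open with the last closed, so an exon included in
#' exactly half the transcripts falls in the upper group.
#'
#' @param exons A tibble of exon features with columns `type` and
#'   `inclusion` (e.g. rows of `gene_models$features`); all rows must be
#'   alternative exons.
#' @param cutoffs Increasing inclusion-fraction cutoffs from 0 to 1.
#' @return The input with `inclusion_group` (1-based index) and
#'   `inclusion_label` columns added.
#' @export
stratify_inclusion <- function(exons, cutoffs = c(0, 0.5, 1)) {
  e <- as_tibble(exons)
  if (!all(c("type", "inclusion") %in% names(e))) {
    abort("exon table needs columns type and inclusion")
  }
  if (any(e$type != "alternative_exon")) {
    abort("stratify_inclusion() applies to alternative exons only")
  }
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    abort("cutoffs must be strictly increasing")
  }
  grp <- findInterval(e$inclusion, cutoffs, rightmost.closed = TRUE)
  labels <- paste0(100 * cutoffs[-length(cutoffs)], "-",
                   100 * cutoffs[-1], "% inclusion")
  e %>% mutate(inclusion_group = grp, inclusion_label = labels[grp])
}
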