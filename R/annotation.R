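#' Build gene models from a transcript exon table
#'
#' Takes a tidy table of exons (one row per exon per transcript) and derives,
#' for every gene, its classified exon features (canonical vs alternative),
#' its introns, the zones where canonical and alternative exons overlap
#' (excluded from all downstream assignment), and per-gene summaries.
#'
#' Canonical exons are exon intervals present in every transcript of the
#' gene; alternative exons are present in some but not all transcripts.
#' Exon identity is exact interval equality; bases shared by two distinct
#' overlapping exon variants (canonical/alternative partial overlaps, or
#' two overlapping alternative variants) have ambiguous class and are
#' recorded as excluded zones. Introns are the maximal gaps between consecutive segments
#' of the merged exon union. Ordinals count features 1-based from the gene's
#' 5' end, respecting strand.
#'
#' All coordinates are 0-based, half-open.
#'
#' @param exons A data frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand` (one row per exon per transcript).
#' @return An object of class `gene_models`: a list of tibbles
#'   `genes` (gene_id, chrom, start, end, strand, n_transcripts, n_exons,
#'   span), `features` (gene_id, chrom, start, end, strand, type, ordinal,
#'   inclusion) where `type` is one of `canonical_exon`, `alternative_exon`,
#'   `intron`, and `excluded` (gene_id, chrom, start, end).
#' @examples
#' ex <- tibble::tibble(
#'   gene_id = "g1", transcript_id = c("t1", "t1", "t1", "t2", "t2"),
#'   chrom = "chr1", start = c(0, 500, 1200, 0, 1200),
#'   end = c(100, 650, 1400, 100, 1400), strand = "+"
#' )
#' gm <- gene_models(ex)
#' gm$features
#' @export
gene_models <- function(exons) {
  exons <- as_tibble(exons)
  req <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(exons))
  if (length(miss) > 0) {
    abort(paste0("exon table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(exons) == 0) abort("no transcripts")
  if (any(exons$start >= exons$end)) abort("exon intervals must satisfy start < end")
  if (!all(exons$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")

  ex_feats <- classify_exons(exons)
  excluded <- attr(ex_feats, "excluded")

  genes <- exons %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      strand = first(.data$strand),
      n_transcripts = n_distinct(.data$transcript_id),
      .groups = "drop"
    ) %>%
    mutate(span = .data$end - .data$start)
  n_ex <- ex_feats %>%
    group_by(.data$gene_id) %>%
    summarise(n_exons = n(), .groups = "drop")
  genes <- left_join(genes, n_ex, by = "gene_id") %>%
    select("gene_id", "chrom", "start", "end", "strand",
           "n_transcripts", "n_exons", "span")

  introns <- derive_introns_tbl(ex_feats)
  features <- bind_rows(ex_feats, introns) %>%
    arrange(.data$gene_id, .data$start)
  attr(features, "excluded") <- NULL

  structure(
    list(genes = genes, features = features, excluded = excluded),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ",
      nrow(x$features), " features (",
      sum(x$features$type == "canonical_exon"), " canonical exons, ",
      sum(x$features$type == "alternative_exon"), " alternative exons, ",
      sum(x$features$type == "intron"), " introns), ",
      nrow(x$excluded), " excluded zones\n", sep = "")
  invisible(x)
}

#' Classify exons as canonical or alternative
#'
#' For each gene, distinct exon intervals are tallied across transcripts.
#' An exon's inclusion fraction is the proportion of the gene's transcripts
#' that contain it (by exact interval equality); canonical exons have
#' inclusion 1, alternative exons inclusion strictly between 0 and 1.
#' Bases shared by distinct overlapping exon variants are returned as
#' excluded zones in the `"excluded"` attribute.
#'
#' @param exons A data frame as for [gene_models()] (a single gene is fine).
#' @return A tibble of exon features (gene_id, chrom, start, end, strand,
#'   type, ordinal, inclusion) with ordinals counted from the 5' end,
#'   carrying an `excluded` attribute (tibble gene_id, chrom, start, end).
#' @export
classify_exons <- function(exons) {
  exons <- as_tibble(exons)
  if (nrow(exons) == 0) abort("no transcripts")

  per_gene <- exons %>%
    group_by(.data$gene_id) %>%
    mutate(.n_tx = n_distinct(.data$transcript_id)) %>%
    ungroup() %>%
    distinct(.data$gene_id, .data$transcript_id, .data$chrom, .data$start,
             .data$end, .data$strand, .data$.n_tx) %>%
    group_by(.data$gene_id, .data$chrom, .data$start, .data$end,
             .data$strand, .data$.n_tx) %>%
    summarise(.n_with = n_distinct(.data$transcript_id), .groups = "drop") %>%
    mutate(
      inclusion = .data$.n_with / .data$.n_tx,
      type = ifelse(.data$inclusion == 1, "canonical_exon", "alternative_exon")
    )

  feats <- per_gene %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .data$end, .by_group = TRUE) %>%
    mutate(ordinal = if (first(.data$strand) == "+") row_number()
                     else rev(row_number())) %>%
    ungroup() %>%
    arrange(.data$gene_id, .data$start) %>%
    select("gene_id", "chrom", "start", "end", "strand", "type",
           "ordinal", "inclusion")

  attr(feats, "excluded") <- overlap_zones(feats)
  feats
}

# bases shared by two distinct exon variants of one gene (canonical vs
# alternative partial overlaps, or two overlapping alternative variants):
# these bases have ambiguous class and are excluded from assignment.
# One coverage pass over all genes, keyed by gene id.
overlap_zones <- function(feats) {
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer())
  if (nrow(feats) < 2) return(empty)
  gr <- GenomicRanges::GRanges(
    feats$gene_id, IRanges::IRanges(feats$start + 1L, feats$end)
  )
  cov <- GenomicRanges::coverage(gr)
  multi <- IRanges::slice(cov, lower = 2, rangesOnly = TRUE)
  n_per <- S4Vectors::elementNROWS(multi)
  if (sum(n_per) == 0) return(empty)
  ir <- unlist(multi, use.names = FALSE)
  gene_id <- rep(names(multi), n_per)
  chrom <- feats$chrom[match(gene_id, feats$gene_id)]
  out <- tibble(
    gene_id = gene_id, chrom = chrom,
    start = BiocGenerics::start(ir) - 1L,
    end = BiocGenerics::end(ir)
  )
  arrange(out, .data$gene_id, .data$start)
}

#' Derive introns from gene models
#'
#' Introns are the maximal gaps between consecutive segments of the union of
#' all exon intervals of a gene, with ordinals assigned 1-based from the
#' gene's 5' end (strand-aware).
#'
#' @param exon_features A tibble of exon features as produced by
#'   [classify_exons()], or a `gene_models` object.
#' @return A tibble of intron features (gene_id, chrom, start, end, strand,
#'   type = "intron", ordinal, inclusion = NA).
#' @export
derive_introns <- function(exon_features) {
  if (inherits(exon_features, "gene_models")) {
    exon_features <- exon_features$features %>%
      filter(.data$type != "intron")
  }
  derive_introns_tbl(exon_features)
}

derive_introns_tbl <- function(ex_feats) {
  empty <- tibble(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), type = character(),
    ordinal = integer(), inclusion = double()
  )
  if (nrow(ex_feats) == 0) return(empty)
  # one reduce over all genes, keyed by gene id; introns are the gaps
  # between consecutive merged exonic segments of each gene
  gr <- GenomicRanges::GRanges(
    ex_feats$gene_id, IRanges::IRanges(ex_feats$start + 1L, ex_feats$end)
  )
  red <- GenomicRanges::reduce(gr)
  d <- tibble(
    gene_id = as.character(GenomicRanges::seqnames(red)),
    start = BiocGenerics::start(red) - 1L,
    end = BiocGenerics::end(red)
  ) %>%
    arrange(.data$gene_id, .data$start)
  n <- nrow(d)
  if (n < 2) return(empty)
  same <- d$gene_id[-1] == d$gene_id[-n]
  if (!any(same)) return(empty)
  introns <- tibble(
    gene_id = d$gene_id[-1][same],
    start = d$end[-n][same],
    end = d$start[-1][same]
  )
  gi <- match(introns$gene_id, ex_feats$gene_id)
  introns$chrom <- ex_feats$chrom[gi]
  introns$strand <- ex_feats$strand[gi]
  introns %>%
    group_by(.data$gene_id) %>%
    mutate(ordinal = if (first(.data$strand) == "+") row_number()
                     else rev(row_number())) %>%
    ungroup() %>%
    mutate(type = "intron", inclusion = NA_real_) %>%
    select("gene_id", "chrom", "start", "end", "strand", "type",
           "ordinal", "inclusion")
}

#' Filter genes by span and exon count
#'
#' Retains genes covering at least `min_span` bases of genomic sequence and
#' containing at least `min_exons` exons. In relaxed mode only the exon-count
#' constraint applies (used for genome-wide analyses where the span
#' constraint is too strict).
#'
#' @param models A `gene_models` object.
#' @param min_span Minimum gene span in bases (default 6000).
#' @param min_exons Minimum number of distinct exons (default 3).
#' @param relaxed If `TRUE`, apply only the exon-count constraint.
#' @return A `gene_models` object restricted to the passing genes.
#' @export
filter_genes <- function(models, min_span = 6000, min_exons = 3,
                         relaxed = FALSE) {
  stopifnot(inherits(models, "gene_models"))
  keep <- models$genes$n_exons >= min_exons
  if (!relaxed) keep <- keep & models$genes$span >= min_span
  ids <- models$genes$gene_id[keep]
  structure(
    list(
      genes = models$genes %>% filter(.data$gene_id %in% ids),
      features = models$features %>% filter(.data$gene_id %in% ids),
      excluded = models$excluded %>% filter(.data$gene_id %in% ids)
    ),
    class = "gene_models"
  )
}

#' Assign tiles (or bins) to gene features by midpoint
#'
#' A tile is assigned to the unique feature that contains its midpoint.
#' Tiles whose midpoint falls in a canonical/alternative overlap zone, or
#' outside every gene, are left unassigned and are absent from the result.
#' The region is `five_prime` when the midpoint lies in the 5'-most 25% of
#' the gene span (strand-aware) and `body` otherwise.
#'
#' When a midpoint is contained in features of more than one overlapping
#' gene, the assignment is deterministic: the feature with the smallest
#' start (then smallest end, then first gene_id) wins.
#'
#' @param tiles A data frame with columns `tile_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param models A `gene_models` object.
#' @param five_prime_fraction Fraction of the gene span counted as the 5'
#'   region (default 0.25).
#' @return A tibble (tile_id, chrom, start, end, midpoint, gene_id, type,
#'   ordinal, inclusion, region) with one row per assigned tile.
#' @export
assign_tiles <- function(tiles, models, five_prime_fraction = 0.25) {
  stopifnot(inherits(models, "gene_models"))
  tiles <- as_tibble(tiles)
  req <- c("tile_id", "chrom", "start", "end")
  miss <- setdiff(req, names(tiles))
  if (length(miss) > 0) {
    abort(paste0("tile table is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tiles$tile_id)) abort("tile_id values must be unique")

  known <- unique(models$features$chrom)
  unknown <- !(tiles$chrom %in% known)
  if (any(unknown)) {
    warn(paste0(sum(unknown), " tile(s) on chromosomes absent from the ",
                "annotation were left unassigned"))
  }
  tiles$midpoint <- (tiles$start + tiles$end) %/% 2L

  feats <- models$features
  gr_feat <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start + 1L, feats$end)
  )
  gr_mid <- GenomicRanges::GRanges(
    tiles$chrom, IRanges::IRanges(tiles$midpoint + 1L, tiles$midpoint + 1L)
  )
  hits <- GenomicRanges::findOverlaps(gr_mid, gr_feat)
  if (length(hits) == 0) {
    return(empty_assignment())
  }
  h <- tibble(
    tile_row = S4Vectors::queryHits(hits),
    feat_row = S4Vectors::subjectHits(hits)
  )
  # deterministic tie-break for overlapping genes: first by feature
  # start, then end, then gene id
  o <- order(h$tile_row, feats$start[h$feat_row], feats$end[h$feat_row],
             feats$gene_id[h$feat_row])
  h <- h[o, ]
  h <- h[!duplicated(h$tile_row), ]

  out <- bind_cols(
    tiles[h$tile_row, c("tile_id", "chrom", "start", "end", "midpoint")],
    feats[h$feat_row, c("gene_id", "type", "ordinal", "inclusion")]
  )

  # drop tiles whose midpoint lies in an excluded canonical/alternative zone
  if (nrow(models$excluded) > 0) {
    gr_ex <- GenomicRanges::GRanges(
      models$excluded$chrom,
      IRanges::IRanges(models$excluded$start + 1L, models$excluded$end)
    )
    gr_mid2 <- GenomicRanges::GRanges(
      out$chrom, IRanges::IRanges(out$midpoint + 1L, out$midpoint + 1L)
    )
    in_ex <- IRanges::overlapsAny(gr_mid2, gr_ex)
    out <- out[!in_ex, ]
  }
  if (nrow(out) == 0) return(empty_assignment())

  genes <- models$genes
  gi <- match(out$gene_id, genes$gene_id)
  cut5 <- five_prime_fraction * genes$span[gi]
  d5 <- ifelse(genes$strand[gi] == "+",
               out$midpoint - genes$start[gi],
               genes$end[gi] - 1L - out$midpoint)
  out$region <- ifelse(d5 < cut5, "five_prime", "body")
  out
}

empty_assignment <- function() {
  tibble(
    tile_id = character(), chrom = character(), start = integer(),
    end = integer(), midpoint = integer(), gene_id = character(),
    type = character(), ordinal = integer(), inclusion = double(),
    region = character()
  )
}
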