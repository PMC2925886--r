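#' Consensus exon-intron metaprofile
#'
#' Averages a Z-score track over ordered feature slots across a consensus
#' gene structure. In `five_prime` mode the slots are exon 1, intron 1,
#' exon 2, ..., exon 10 (first ten exons and nine introns); in
#' `three_prime` mode the last five exons and four introns, counted from
#' the 3' end. Genes with fewer features contribute to as many slots as
#' they have. Profiles use canonical exons only; alternative exons are
#' summarized separately by [class_means()]. Each slot reports the mean
#' tile Z (tiles weighted equally), the number of tiles, and a 95%
#' normal-approximation confidence half-width.
#'
#' @param track A Z-score `tile_track` (or counts track for ChIP-seq).
#' @param assignment Tile/bin assignment from [assign_tiles()] or
#'   [assign_bins()].
#' @param models The `gene_models` the assignment was made against (needed
#'   in `three_prime` mode to count features from the 3' end).
#' @param mode `"five_prime"` (default) or `"three_prime"`.
#' @param gene_set Optional character vector of gene ids to restrict to
#'   (e.g. the ON genes).
#' @param n_exon_slots Number of exon slots (default 10 in 5' mode, 5 in
#'   3' mode).
#' @return A `meta_profile`: tibble (slot, feature, ordinal, mean_z, n, ci)
#'   ordered 5' to 3', with attribute `mode`.
#' @export
exon_intron_profile <- function(track, assignment, models = NULL,
                                mode = c("five_prime", "three_prime"),
                                gene_set = NULL, n_exon_slots = NULL) {
  mode <- match.arg(mode)
  if (is.null(n_exon_slots)) {
    n_exon_slots <- if (mode == "five_prime") 10L else 5L
  }
  n_intron_slots <- n_exon_slots - 1L
  asn <- joined_assignment(track, assignment, gene_set)
  if (nrow(asn) == 0) abort("empty gene set")

  asn <- asn %>% filter(.data$type %in% c("canonical_exon", "intron"))
  if (mode == "three_prime") {
    if (is.null(models)) abort("three_prime mode needs the gene_models object")
    asn <- add_rev_ordinals(asn, models)
    asn$use_ordinal <- asn$rev_ordinal
  } else {
    asn$use_ordinal <- asn$ordinal
  }
  asn <- asn %>%
    filter((.data$type == "canonical_exon" &
              .data$use_ordinal <= n_exon_slots) |
             (.data$type == "intron" & .data$use_ordinal <= n_intron_slots))

  slots <- slot_frame(n_exon_slots, mode)
  stats <- asn %>%
    mutate(feature = ifelse(.data$type == "canonical_exon",
                            "exon", "intron")) %>%
    group_by(.data$feature, .data$use_ordinal) %>%
    summarise(
      mean_z = mean(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      ci = 1.96 * sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      .groups = "drop"
    ) %>%
    rename(ordinal = "use_ordinal")
  out <- slots %>%
    left_join(stats, by = c("feature", "ordinal")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  structure(out, mode = mode,
            class = c("meta_profile", class(tibble())))
}

slot_frame <- function(n_exon_slots, mode) {
  feature <- character(0)
  ordinal <- integer(0)
  if (mode == "five_prime") {
    for (k in seq_len(n_exon_slots)) {
      feature <- c(feature, "exon")
      ordinal <- c(ordinal, k)
      if (k < n_exon_slots) {
        feature <- c(feature, "intron")
        ordinal <- c(ordinal, k)
      }
    }
    lab <- paste0(feature, ordinal)
  } else {
    # ordinal 1 = last feature of the gene; slots presented 5' -> 3'
    for (k in rev(seq_len(n_exon_slots))) {
      feature <- c(feature, "exon")
      ordinal <- c(ordinal, k)
      if (k > 1) {
        feature <- c(feature, "intron")
        ordinal <- c(ordinal, k - 1L)
      }
    }
    lab <- ifelse(ordinal == 1, paste0(feature, "_last"),
                  paste0(feature, "_last-", ordinal - 1L))
  }
  tibble(slot = factor(lab, levels = lab), feature = feature,
         ordinal = ordinal)
}

# join track values onto an assignment, optionally restricting genes
joined_assignment <- function(track, assignment, gene_set = NULL) {
  v <- track_values(track)
  asn <- as_tibble(assignment)
  if (!is.null(gene_set)) asn <- asn %>% filter(.data$gene_id %in% gene_set)
  asn %>%
    inner_join(v, by = "tile_id") %>%
    filter(!is.na(.data$value))
}

# reverse (3'-counted) ordinals: 1 = last feature of the gene
add_rev_ordinals <- function(asn, models) {
  counts <- models$features %>%
    mutate(kind = ifelse(.data$type == "intron", "intron", "exon")) %>%
    group_by(.data$gene_id, .data$kind) %>%
    summarise(n_feat = n(), .groups = "drop")
  asn %>%
    mutate(kind = ifelse(.data$type == "intron", "intron", "exon")) %>%
    left_join(counts, by = c("gene_id", "kind")) %>%
    mutate(rev_ordinal = .data$n_feat - .data$ordinal + 1L)
}

#' Feature-class means, confidence intervals and the exon-intron bias
#'
#' Mean Z per feature class (canonical exons, alternative exons, introns),
#' optionally split into 5' and body regions, with 95% confidence
#' intervals (mean +/- 1.96 * SD / sqrt(n)). The exon-intron marking bias
#' is summarized as delta Z = canonical-exon mean minus intron mean;
#' positive values reflect exon biases, negative values intron biases.
#'
#' @inheritParams exon_intron_profile
#' @param region_split Split classes into `five_prime` and `body` regions.
#' @return A `class_summary`: list with `summary` (tibble: class, region,
#'   mean_z, n, ci) and `delta` (tibble: region, delta_z). `region` is
#'   `"all"` when not split.
#' @export
class_means <- function(track, assignment, gene_set = NULL,
                        region_split = FALSE) {
  asn <- joined_assignment(track, assignment, gene_set)
  if (nrow(asn) == 0) abort("empty gene set")
  if (!region_split) asn$region <- "all"
  classes <- c("canonical_exon", "alternative_exon", "intron")
  grid <- tidyr::expand_grid(type = classes,
                             region = unique(asn$region))
  stats <- asn %>%
    group_by(.data$type, .data$region) %>%
    summarise(
      mean_z = mean(.data$value),
      n = n(),
      ci = 1.96 * sd(.data$value) / sqrt(n()),
      .groups = "drop"
    )
  summary <- grid %>%
    left_join(stats, by = c("type", "region")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    arrange(.data$region, match(.data$type, classes))
  delta <- summary %>%
    select("type", "region", "mean_z") %>%
    tidyr::pivot_wider(names_from = "type", values_from = "mean_z") %>%
    mutate(delta_z = .data$canonical_exon - .data$intron) %>%
    select("region", "delta_z")
  structure(list(summary = summary, delta = delta),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("<class_summary>\n")
  print(x$summary)
  cat("delta Z (canonical exon - intron; + = exon bias):\n")
  print(x$delta)
  invisible(x)
}

#' Proportional gene-length profile with flanks
#'
#' Maps each tile midpoint to a strand-aware position on a
#' flank-gene-flank percentage axis: 0-100% spans the gene body 5' to 3',
#' negative percentages the upstream flank and values above 100% the
#' downstream flank (each flank `flank_fraction` of the gene span). Mean Z
#' is reported per percentage bin across all genes; a tile flanking two
#' genes contributes to both.
#'
#' @inheritParams exon_intron_profile
#' @param tiles Tile table (tile_id, chrom, start, end).
#' @param n_bins Total number of bins across the whole axis (default 40).
#' @param flank_fraction Flank size as a fraction of gene span
#'   (default 0.5, i.e. the axis runs -50% to 150%).
#' @return A `gene_percent_profile`: tibble (bin, bin_mid, mean_z, n).
#' @export
gene_percent_profile <- function(track, tiles, models, gene_set = NULL,
                                 n_bins = 40, flank_fraction = 0.5) {
  stopifnot(inherits(models, "gene_models"))
  v <- track_values(track)
  tiles <- as_tibble(tiles)
  tiles$midpoint <- (tiles$start + tiles$end) %/% 2L
  genes <- models$genes
  if (!is.null(gene_set)) genes <- genes %>% filter(.data$gene_id %in% gene_set)

  lo <- -100 * flank_fraction
  hi <- 100 * (1 + flank_fraction)
  edges <- seq(lo, hi, length.out = n_bins + 1)

  rel <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ext_start <- g$start - flank_fraction * g$span
    ext_end <- g$end + flank_fraction * g$span
    sel <- tiles$chrom == g$chrom &
      tiles$midpoint >= ext_start & tiles$midpoint < ext_end
    if (!any(sel)) return(tibble(tile_id = character(), rel = double()))
    mid <- tiles$midpoint[sel]
    r <- if (g$strand == "+") {
      100 * (mid - g$start) / g$span
    } else {
      100 * (g$end - mid) / g$span
    }
    tibble(tile_id = tiles$tile_id[sel], rel = r)
  })
  rel <- rel %>%
    inner_join(v, by = "tile_id") %>%
    filter(!is.na(.data$value)) %>%
    mutate(bin = pmin(pmax(findInterval(.data$rel, edges,
                                        rightmost.closed = TRUE), 1L),
                      n_bins))
  out <- tibble(bin = seq_len(n_bins),
                bin_mid = (edges[-1] + edges[-length(edges)]) / 2) %>%
    left_join(
      rel %>%
        group_by(.data$bin) %>%
        summarise(mean_z = mean(.data$value), n = n(), .groups = "drop"),
      by = "bin"
    ) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  structure(out, flank_fraction = flank_fraction,
            class = c("gene_percent_profile", class(tibble())))
}
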