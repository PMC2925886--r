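#' Bin aligned reads into fixed-width genomic bins
#'
#' Each read increments exactly one bin: the bin containing its 5' start
#' (the `start` coordinate on the plus strand, `end - 1` on the minus
#' strand; reads without strand are treated as plus). Bins are half-open
#' `[k * bin_size, (k + 1) * bin_size)`.
#'
#' @param reads A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @param bin_size Bin width in bases (default 200).
#' @return A `bin_track`: a tibble (chrom, bin, start, end, count) with one
#'   row per non-empty bin and attribute `bin_size`. Total count equals the
#'   number of reads.
#' @export
bin_reads <- function(reads, bin_size = 200) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0) {
    abort("bin_size must be a positive number")
  }
  bin_size <- as.integer(bin_size)
  r <- as_tibble(reads)
  if (nrow(r) == 0) {
    out <- tibble(chrom = character(), bin = integer(),
                  start = integer(), end = integer(), count = integer())
    return(structure(out, bin_size = bin_size,
                     class = c("bin_track", class(tibble()))))
  }
  five <- if ("strand" %in% names(r)) {
    ifelse(r$strand == "-", r$end - 1L, r$start)
  } else {
    r$start
  }
  out <- tibble(chrom = r$chrom, bin = as.integer(five %/% bin_size)) %>%
    group_by(.data$chrom, .data$bin) %>%
    summarise(count = n(), .groups = "drop") %>%
    mutate(start = .data$bin * bin_size,
           end = (.data$bin + 1L) * bin_size) %>%
    select("chrom", "bin", "start", "end", "count") %>%
    arrange(.data$chrom, .data$bin)
  structure(out, bin_size = bin_size,
            class = c("bin_track", class(tibble())))
}

#' Assign genomic bins to gene features
#'
#' Bins are assigned to canonical/alternative exons and introns by the same
#' midpoint rule as array tiles ([assign_tiles()]), carrying their read
#' counts, so ChIP-seq data flows into the same downstream feature
#' statistics as ChIP-chip. Bins whose midpoint falls in a
#' canonical/alternative overlap zone or outside every gene are absent.
#'
#' @param bins A `bin_track` from [bin_reads()].
#' @param models A `gene_models` object.
#' @return A tibble as from [assign_tiles()] with an extra `count` column
#'   (reads in the bin).
#' @export
assign_bins <- function(bins, models) {
  b <- as_tibble(bins)
  b$tile_id <- paste0(b$chrom, ":", b$start, "-", b$end)
  asn <- assign_tiles(b[, c("tile_id", "chrom", "start", "end")], models)
  left_join(asn, b[, c("tile_id", "count")], by = "tile_id")
}

#' Mean reads per bin by feature class and ordinal
#'
#' @param assignment Output of [assign_bins()].
#' @return A tibble (type, ordinal, mean_count, n_bins).
#' @export
bin_feature_means <- function(assignment) {
  as_tibble(assignment) %>%
    group_by(.data$type, .data$ordinal) %>%
    summarise(mean_count = mean(.data$count), n_bins = n(),
              .groups = "drop") %>%
    arrange(.data$type, .data$ordinal)
}

#' Convert a bin track to a tile track of counts
#'
#' Lets ChIP-seq bin counts run through the feature statistics and the
#' coordinate-randomization bootstrap exactly like array tracks. Bins with
#' zero reads inside the covered extent are included with count 0 so the
#' randomization domain is the full analyzed region.
#'
#' @param bins A `bin_track`.
#' @param fill_gaps If `TRUE` (default), include zero-count bins between
#'   the first and last non-empty bin of each chromosome.
#' @return A `tile_track` with `state = "counts"` and tile ids
#'   `chrom:start-end`, plus columns usable as a tile table.
#' @export
bin_track_values <- function(bins, fill_gaps = TRUE) {
  b <- as_tibble(bins)
  bin_size <- attr(bins, "bin_size")
  if (fill_gaps && nrow(b) > 0) {
    b <- b %>%
      group_by(.data$chrom) %>%
      group_modify(function(df, key) {
        full <- tibble(bin = seq(min(df$bin), max(df$bin)))
        full %>%
          left_join(df[, c("bin", "count")], by = "bin") %>%
          mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
                 start = .data$bin * bin_size,
                 end = (.data$bin + 1L) * bin_size)
      }) %>%
      ungroup()
  }
  tt <- tile_track(
    tibble(tile_id = paste0(b$chrom, ":", b$start, "-", b$end),
           value = as.numeric(b$count)),
    state = "counts", assay = "chip_seq"
  )
  attr(tt, "bins") <- b
  tt
}

#' Bin table usable as a tile table
#'
#' @param bins A `bin_track`.
#' @param fill_gaps Include zero-count bins (see [bin_track_values()]).
#' @return A tibble (tile_id, chrom, start, end, count).
#' @export
bins_as_tiles <- function(bins, fill_gaps = TRUE) {
  tt <- bin_track_values(bins, fill_gaps = fill_gaps)
  b <- attr(tt, "bins")
  tibble(tile_id = paste0(b$chrom, ":", b$start, "-", b$end),
         chrom = b$chrom, start = as.integer(b$start),
         end = as.integer(b$end), count = b$count)
}
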