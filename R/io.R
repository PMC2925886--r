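#' Read a gene annotation from GFF3 or GTF
#'
#' Imports exon records and their gene/transcript grouping into the tidy
#' exon table consumed by [gene_models()]. GFF3 files are expected to carry
#' gene, mRNA/transcript and exon records linked by `ID`/`Parent`; GTF
#' files the usual `gene_id`/`transcript_id` attributes. Coordinates are
#' converted to the package's 0-based half-open convention on read.
#'
#' @param path Path to a `.gff3`/`.gff` or `.gtf` file.
#' @return A tibble (gene_id, transcript_id, chrom, start, end, strand).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  ex <- df[tolower(df$type) == "exon", ]
  if (nrow(ex) == 0) abort("no exon records in annotation file")

  if (!is.null(ex$transcript_id) && !is.null(ex$gene_id)) {
    tx_id <- as.character(ex$transcript_id)
    gene_id <- as.character(ex$gene_id)
  } else {
    # GFF3: exon Parent -> transcript; transcript Parent -> gene
    parent <- vapply(ex$Parent, function(p) as.character(p)[1], character(1))
    tx <- df[tolower(df$type) %in% c("mrna", "transcript"), ]
    tx_gene <- setNames(
      vapply(tx$Parent, function(p) as.character(p)[1], character(1)),
      as.character(tx$ID)
    )
    tx_id <- parent
    gene_id <- unname(tx_gene[parent])
    if (anyNA(gene_id)) abort("could not resolve gene ids from GFF3 Parent links")
  }
  tibble(
    gene_id = gene_id, transcript_id = tx_id,
    chrom = as.character(ex$seqnames),
    start = ex$start - 1L, end = ex$end,
    strand = as.character(ex$strand)
  ) %>%
    arrange(.data$gene_id, .data$transcript_id, .data$start)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and exon records (1-based inclusive coordinates, as
#' GFF3 requires) for a transcript exon table or a `sim_annotation`.
#'
#' @param exons A transcript exon table (as for [gene_models()]) or a
#'   `sim_annotation`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(exons, path) {
  if (inherits(exons, "sim_annotation")) exons <- exons$exons
  exons <- as_tibble(exons)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- exons %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              .groups = "drop")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\texonmark\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
               con)
    gex <- exons %>% filter(.data$gene_id == g$gene_id)
    for (tx in unique(gex$transcript_id)) {
      tex <- gex %>% filter(.data$transcript_id == tx) %>%
        arrange(.data$start)
      writeLines(sprintf(
        "%s\texonmark\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        g$chrom, min(tex$start) + 1L, max(tex$end), g$strand, tx, g$gene_id
      ), con)
      writeLines(sprintf(
        "%s\texonmark\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        tex$chrom, tex$start + 1L, tex$end, tex$strand, tx
      ), con)
    }
  }
  invisible(path)
}

#' Read and write tab-delimited tile measurement tables
#'
#' Columns: tile_id, chrom, start, end, replicate, chip, chip_bg, input,
#' input_bg, flag.
#'
#' @param path File path.
#' @return `read_measurements()` returns a tibble; `write_measurements()`
#'   the path, invisibly.
#' @export
read_measurements <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE)) %>%
    mutate(tile_id = as.character(.data$tile_id))
}

#' @rdname read_measurements
#' @param measurements Measurement tibble.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write BED6 read/interval files
#'
#' BED is 0-based half-open, matching the package convention.
#'
#' @param path File path.
#' @return `read_bed()` returns a tibble (chrom, start, end, name, score,
#'   strand); `write_bed()` the path, invisibly.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- cols[seq_len(ncol(df))]
  as_tibble(df)
}

#' @rdname read_bed
#' @param intervals Interval tibble with at least chrom, start, end.
#' @export
write_bed <- function(intervals, path) {
  d <- as_tibble(intervals)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(d))
  utils::write.table(d[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a feature assignment as BED
#'
#' One record per assigned tile with name `gene|class|ordinal|region`.
#'
#' @param assignment Output of [assign_tiles()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_assignment_bed <- function(assignment, path) {
  a <- as_tibble(assignment)
  write_bed(
    a %>% mutate(
      name = paste(.data$gene_id, .data$type, .data$ordinal, .data$region,
                   sep = "|"),
      score = 0L, strand = "."
    ),
    path
  )
}

#' Write a track as bedGraph or fixed-step wiggle
#'
#' Tracks are written against a tile table supplying the coordinates of
#' each tile id. Missing values are skipped. The wiggle writer emits one
#' `fixedStep` block per run of contiguous equal-width tiles, for viewing
#' in a genome browser.
#'
#' @param track A `tile_track`.
#' @param tiles Tile table (tile_id, chrom, start, end).
#' @param path Output path.
#' @param name Track name for the header line.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, tiles, path, name = "exonmark") {
  v <- track_values(track)
  d <- as_tibble(tiles) %>%
    inner_join(v, by = "tile_id") %>%
    filter(!is.na(.data$value)) %>%
    arrange(.data$chrom, .data$start)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  writeLines(sprintf("%s\t%d\t%d\t%.6g", d$chrom, d$start, d$end, d$value),
             con)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
write_wiggle <- function(track, tiles, path, name = "exonmark") {
  v <- track_values(track)
  d <- as_tibble(tiles) %>%
    inner_join(v, by = "tile_id") %>%
    filter(!is.na(.data$value)) %>%
    arrange(.data$chrom, .data$start)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
  if (nrow(d) == 0) return(invisible(path))
  width <- d$end - d$start
  new_block <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                   d$start[-1] != d$end[-nrow(d)] |
                   width[-1] != width[-nrow(d)])
  block <- cumsum(new_block)
  for (b in unique(block)) {
    i <- which(block == b)
    writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                       d$chrom[i[1]], d$start[i[1]] + 1L, width[i[1]],
                       width[i[1]]), con)
    writeLines(sprintf("%.6g", d$value[i]), con)
  }
  invisible(path)
}

#' Read and write expression tables
#'
#' Tab-delimited gene-by-value tables with a header; the status column
#' (when present) uses ON/OFF/NA.
#'
#' @param path File path.
#' @return `read_expression()` returns a tibble; `write_expression()` the
#'   path, invisibly.
#' @export
read_expression <- function(path) {
  e <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if ("status" %in% names(e)) {
    e$status[is.na(e$status)] <- "neither"
  }
  e
}

#' @rdname read_expression
#' @param expression Expression tibble.
#' @export
write_expression <- function(expression, path) {
  e <- as_tibble(expression)
  if ("status" %in% names(e)) e$status[e$status == "neither"] <- NA
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bin track as bedGraph
#'
#' @param bins A `bin_track`.
#' @param path Output path.
#' @param name Track name.
#' @return The path, invisibly.
#' @export
write_bin_bedgraph <- function(bins, path, name = "exonmark_bins") {
  b <- as_tibble(bins)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  writeLines(sprintf("%s\t%d\t%d\t%d", b$chrom, b$start, b$end, b$count),
             con)
  invisible(path)
}
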