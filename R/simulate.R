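#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the simulator with defaults that emulate the kind
#' of data the analysis was designed for: multi-exon genes (uniform 3-12
#' exons, lognormal exon lengths with median 150 b and intron lengths with
#' median 1500 b, 1-4 transcripts per gene), a contiguous 500-b tiling
#' emulating a PCR-product array (a 200-b tile length emulates the ChIP-seq
#' bin scale), 36-b reads, three bioreplicates and lognormal replicate noise
#' with SD 0.3 on the log2 scale.
#'
#' Truth is planted in ratio space: the generator constructs channel
#' intensities so that the preprocessing chain recovers the configured
#' per-feature log2 enrichment exactly at zero noise (see
#' [simulate_chipchip()]).
#'
#' @param seed Integer seed; every generator draws from it deterministically.
#' @param n_genes Number of genes.
#' @param exon_count Integer range (min, max) of exons per gene.
#' @param exon_len_meanlog,exon_len_sdlog Lognormal exon length parameters.
#' @param intron_len_meanlog,intron_len_sdlog Lognormal intron length
#'   parameters.
#' @param transcripts Integer range (min, max) of transcripts per gene.
#' @param alt_prob Probability that an internal exon of a multi-transcript
#'   gene is variably included.
#' @param intergenic_gap Bases between consecutive genes.
#' @param tile_length Tile width in bases (contiguous tiling).
#' @param read_length Read length in bases.
#' @param baseline_log2 Baseline log2 enrichment of every tile.
#' @param exon_effect Added log2 enrichment on canonical exons (delta E).
#' @param intron_effect Added log2 enrichment on introns (delta I).
#' @param alt_coupling `"inclusion_weighted"` (alternative exons get
#'   `inclusion * exon_effect`) or `"independent"` (full `exon_effect`).
#' @param density_exon_mult,density_intron_mult Nucleosome-density
#'   multipliers on exons/introns (the confound track's own bias).
#' @param igg_baseline Relative level of the IgG control.
#' @param noise_sd Replicate noise SD on the log2 scale (lognormal factor).
#' @param n_replicates Bioreplicates per assay.
#' @param expression_meanlog,expression_sdlog Lognormal per-gene expression.
#' @param expression_coupling In `[0, 1]`: 0 decouples marks from
#'   expression; 1 scales a gene's exon effect by its expression decile
#'   (`decile / 10`), giving a monotone mark-expression relationship.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 50,
                       exon_count = c(3, 12),
                       exon_len_meanlog = log(150), exon_len_sdlog = 0.4,
                       intron_len_meanlog = log(1500), intron_len_sdlog = 0.6,
                       transcripts = c(1, 4), alt_prob = 0.3,
                       intergenic_gap = 4000,
                       tile_length = 500, read_length = 36,
                       baseline_log2 = 0, exon_effect = 0, intron_effect = 0,
                       alt_coupling = c("inclusion_weighted", "independent"),
                       density_exon_mult = 1, density_intron_mult = 1,
                       igg_baseline = 1, noise_sd = 0.3, n_replicates = 3,
                       expression_meanlog = 3, expression_sdlog = 1,
                       expression_coupling = 0) {
  alt_coupling <- match.arg(alt_coupling)
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exon_count = as.integer(exon_count),
    exon_len_meanlog = exon_len_meanlog, exon_len_sdlog = exon_len_sdlog,
    intron_len_meanlog = intron_len_meanlog,
    intron_len_sdlog = intron_len_sdlog,
    transcripts = as.integer(transcripts), alt_prob = alt_prob,
    intergenic_gap = as.integer(intergenic_gap),
    tile_length = as.integer(tile_length),
    read_length = as.integer(read_length),
    baseline_log2 = baseline_log2, exon_effect = exon_effect,
    intron_effect = intron_effect, alt_coupling = alt_coupling,
    density_exon_mult = density_exon_mult,
    density_intron_mult = density_intron_mult,
    igg_baseline = igg_baseline, noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates),
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    expression_coupling = expression_coupling,
    ref_intensity = 1000, background = 100
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) abort("n_genes must be positive")
  if (length(cfg$exon_count) != 2 || cfg$exon_count[1] < 1 ||
      cfg$exon_count[1] > cfg$exon_count[2]) {
    abort("infeasible exon count range")
  }
  if (length(cfg$transcripts) != 2 || cfg$transcripts[1] < 1 ||
      cfg$transcripts[1] > cfg$transcripts[2]) {
    abort("infeasible transcript count range")
  }
  if (cfg$tile_length < 1 || cfg$read_length < 1 || cfg$intergenic_gap < 0) {
    abort("infeasible length constraints")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be non-negative")
  if (cfg$alt_prob < 0 || cfg$alt_prob > 1 ||
      cfg$expression_coupling < 0 || cfg$expression_coupling > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  if (cfg$density_exon_mult <= 0 || cfg$density_intron_mult <= 0 ||
      cfg$igg_baseline <= 0) {
    abort("density and IgG multipliers must be positive")
  }
  invisible(cfg)
}

#' Simulate a multi-transcript gene annotation
#'
#' Lays genes end to end along one chromosome (alternating strands),
#' drawing exon counts, exon lengths and intron lengths from the
#' configured distributions. Multi-transcript genes mark internal exons as
#' variably included with probability `alt_prob`; each variable exon is
#' kept in a random non-empty proper subset of transcripts, producing
#' alternative exons with known inclusion fractions. First and last exons
#' are shared by all transcripts so the gene span is transcript-invariant.
#'
#' @param config A [sim_config()].
#' @return A `sim_annotation`: list with `exons` (transcript exon table),
#'   `models` (a `gene_models`) and `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pos <- 0L
  rows <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    n_ex <- sample(seq(config$exon_count[1], config$exon_count[2]), 1)
    ex_len <- pmax(20L, as.integer(ceiling(
      rlnorm(n_ex, config$exon_len_meanlog, config$exon_len_sdlog))))
    in_len <- if (n_ex > 1) {
      pmax(50L, as.integer(ceiling(
        rlnorm(n_ex - 1, config$intron_len_meanlog,
               config$intron_len_sdlog))))
    } else {
      integer(0)
    }
    starts <- pos + cumsum(c(0L, head(ex_len, -1) + in_len))
    ends <- starts + ex_len
    strand <- sample(c("+", "-"), 1)
    n_tx <- sample(seq(config$transcripts[1], config$transcripts[2]), 1)

    # which exons are variably included (internal exons only)
    variable <- rep(FALSE, n_ex)
    if (n_tx > 1 && n_ex > 2) {
      variable[2:(n_ex - 1)] <- runif(n_ex - 2) < config$alt_prob
    }
    gene_id <- sprintf("g%04d", i)
    # choose, per variable exon, the subset of transcripts that keep it
    keep_mat <- matrix(TRUE, nrow = n_tx, ncol = n_ex)
    for (e in which(variable)) {
      k <- sample(seq_len(n_tx - 1), 1) # 1 .. n_tx-1 transcripts keep it
      keep_mat[, e] <- FALSE
      keep_mat[sample(seq_len(n_tx), k), e] <- TRUE
    }
    g_rows <- purrr::map_dfr(seq_len(n_tx), function(t) {
      sel <- keep_mat[t, ]
      tibble(
        gene_id = gene_id,
        transcript_id = sprintf("%s.t%d", gene_id, t),
        chrom = "chr1",
        start = starts[sel], end = ends[sel], strand = strand
      )
    })
    rows[[i]] <- g_rows
    pos <- max(ends) + config$intergenic_gap
  }
  exons <- bind_rows(rows)
  structure(
    list(exons = exons, models = gene_models(exons), config = config),
    class = "sim_annotation"
  )
}

#' Tile layout covering a simulated annotation
#'
#' Contiguous tiles of `tile_length` bases from coordinate 0 to just past
#' the last gene on each chromosome.
#'
#' @param annotation A `sim_annotation` (or `gene_models`).
#' @param tile_length Tile width; defaults to the annotation's configured
#'   tile length.
#' @return A tile table (tile_id, chrom, start, end).
#' @export
tile_layout <- function(annotation, tile_length = NULL) {
  models <- if (inherits(annotation, "sim_annotation")) annotation$models
            else annotation
  if (is.null(tile_length)) {
    tile_length <- if (inherits(annotation, "sim_annotation")) {
      annotation$config$tile_length
    } else {
      500L
    }
  }
  models$genes %>%
    group_by(.data$chrom) %>%
    summarise(chrom_end = max(.data$end), .groups = "drop") %>%
    group_by(.data$chrom) %>%
    group_modify(function(df, key) {
      n_tiles <- ceiling((df$chrom_end + tile_length) / tile_length)
      tibble(start = as.integer((seq_len(n_tiles) - 1) * tile_length)) %>%
        mutate(end = .data$start + as.integer(tile_length))
    }) %>%
    ungroup() %>%
    mutate(tile_id = sprintf("t%06d", row_number())) %>%
    select("tile_id", "chrom", "start", "end")
}

# per-tile truth: feature class, inclusion, density multiplier and true
# log2 enrichment under the configured effects
tile_truth <- function(config, annotation, tiles, expression = NULL) {
  asn <- assign_tiles(tiles, annotation$models)
  truth <- tiles %>%
    left_join(asn[, c("tile_id", "gene_id", "type", "inclusion")],
              by = "tile_id") %>%
    mutate(class = ifelse(is.na(.data$type), "intergenic", .data$type))

  exon_mult <- rep(1, nrow(truth))
  if (!is.null(expression) && config$expression_coupling > 0) {
    dec <- expression$decile[match(truth$gene_id, expression$gene_id)]
    cpl <- config$expression_coupling
    exon_mult <- ifelse(is.na(dec), 1, (1 - cpl) + cpl * dec / 10)
  }
  alt_scale <- if (config$alt_coupling == "inclusion_weighted") {
    ifelse(is.na(truth$inclusion), 1, truth$inclusion)
  } else {
    rep(1, nrow(truth))
  }
  truth %>%
    mutate(
      true_log2 = config$baseline_log2 + case_when(
        .data$class == "canonical_exon" ~ config$exon_effect * exon_mult,
        .data$class == "alternative_exon" ~
          config$exon_effect * exon_mult * alt_scale,
        .data$class == "intron" ~ config$intron_effect,
        TRUE ~ 0
      ),
      density = case_when(
        .data$class %in% c("canonical_exon", "alternative_exon") ~
          config$density_exon_mult,
        .data$class == "intron" ~ config$density_intron_mult,
        TRUE ~ 1
      )
    ) %>%
    select("tile_id", "chrom", "start", "end", "gene_id", "class",
           "inclusion", "true_log2", "density")
}

#' Simulate two-channel tiled-array measurements
#'
#' Emits raw measurement tables for a histone-modification assay together
#' with its confound and control assays (H2B, H3 histone density; IgG),
#' three bioreplicates each by default. Truth is planted in ratio space:
#' the input channel is flat genomic reference, the modification ChIP
#' channel is `reference * density * 2^(true_log2) * noise`, the density
#' assays carry `reference * density * noise` and IgG
#' `reference * igg_baseline * noise`, all plus a constant additive
#' background that the background correction removes. At zero noise the
#' preprocessing chain therefore recovers the configured exon/intron log2
#' effects exactly, and dividing by the combined H2B/H3 density composite
#' removes the nucleosome-density confound exactly.
#'
#' @param config A [sim_config()].
#' @param annotation A `sim_annotation` from [simulate_annotation()].
#' @param tiles Optional tile table (defaults to [tile_layout()]).
#' @param expression Optional expression truth from
#'   [simulate_expression()], used when `expression_coupling > 0`.
#' @return A `sim_chipchip`: list with `measurements` (named list of
#'   tibbles `mod`, `h2b`, `h3`, `igg`), `truth` (per-tile truth) and
#'   `tiles`.
#' @export
simulate_chipchip <- function(config, annotation, tiles = NULL,
                              expression = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "sim_annotation"))
  if (is.null(tiles)) tiles <- tile_layout(annotation)
  truth <- tile_truth(config, annotation, tiles, expression)
  set.seed(config$seed + 1L)

  ref <- config$ref_intensity
  bg <- config$background
  n_tiles <- nrow(truth)

  emit <- function(mean_level) {
    purrr::map_dfr(seq_len(config$n_replicates), function(r) {
      noise <- 2^rnorm(n_tiles, 0, config$noise_sd)
      tibble(
        tile_id = truth$tile_id, chrom = truth$chrom,
        start = truth$start, end = truth$end,
        replicate = r,
        chip = ref * mean_level * noise + bg, chip_bg = bg,
        input = ref + bg, input_bg = bg,
        flag = "ok"
      )
    })
  }
  measurements <- list(
    mod = emit(truth$density * 2^truth$true_log2),
    h2b = emit(truth$density),
    h3 = emit(truth$density),
    igg = emit(rep(config$igg_baseline, n_tiles))
  )
  structure(list(measurements = measurements, truth = truth, tiles = tiles),
            class = "sim_chipchip")
}

#' Simulate aligned short reads
#'
#' Draws read 5' start positions from a per-base intensity proportional to
#' the configured occupancy (feature density multipliers times the
#' configured log2 enrichment effects), honouring the requested read count
#' exactly. Reads are `read_length` bases, plus strand, BED-style.
#'
#' @param config A [sim_config()].
#' @param annotation A `sim_annotation`.
#' @param n_reads Number of reads to emit.
#' @param weights Optional named occupancy multipliers
#'   (`canonical_exon`, `alternative_exon`, `intron`, `intergenic`)
#'   overriding the config-derived occupancy.
#' @return A tibble (chrom, start, end, name, score, strand).
#' @export
simulate_reads <- function(config, annotation, n_reads = 10000,
                           weights = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "sim_annotation"))
  segs <- read_segments(config, annotation)
  set.seed(config$seed + 2L)

  w <- if (is.null(weights)) {
    segs$density * 2^segs$true_log2
  } else {
    unname(unlist(weights)[segs$class])
  }
  if (any(is.na(w) | w < 0)) abort("invalid occupancy weights")
  if (all(w == 0)) abort("occupancy is zero everywhere")
  len <- segs$end - segs$start
  seg <- sample(seq_len(nrow(segs)), n_reads, replace = TRUE,
                prob = w * len)
  offset <- floor(runif(n_reads) * len[seg])
  start <- segs$start[seg] + as.integer(offset)
  tibble(
    chrom = segs$chrom[seg], start = start,
    end = start + config$read_length,
    name = sprintf("read%07d", seq_len(n_reads)),
    score = 0L, strand = "+"
  ) %>%
    arrange(.data$chrom, .data$start)
}

# per-base occupancy segments: every annotated feature plus the intergenic
# gaps between them, with the density/enrichment each class carries
read_segments <- function(config, annotation) {
  feats <- annotation$models$features
  alt_scale <- if (config$alt_coupling == "inclusion_weighted") {
    ifelse(is.na(feats$inclusion), 1, feats$inclusion)
  } else {
    rep(1, nrow(feats))
  }
  fseg <- tibble(
    chrom = feats$chrom, start = feats$start, end = feats$end,
    class = feats$type,
    true_log2 = config$baseline_log2 + case_when(
      feats$type == "canonical_exon" ~ config$exon_effect,
      feats$type == "alternative_exon" ~ config$exon_effect * alt_scale,
      TRUE ~ config$intron_effect
    ),
    density = ifelse(feats$type == "intron", config$density_intron_mult,
                     config$density_exon_mult)
  )
  gaps <- fseg %>%
    group_by(.data$chrom) %>%
    group_modify(function(df, key) {
      ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
      gp <- IRanges::gaps(ir, start = 1L, end = max(BiocGenerics::end(ir)))
      tibble(start = BiocGenerics::start(gp) - 1L,
             end = BiocGenerics::end(gp))
    }) %>%
    ungroup() %>%
    mutate(class = "intergenic", true_log2 = config$baseline_log2,
           density = 1)
  bind_rows(fseg, gaps) %>%
    arrange(.data$chrom, .data$start)
}

#' Simulate per-gene expression values
#'
#' Lognormal per-gene expression with known decile (1 = lowest). When
#' `expression_coupling > 0` in the config, [simulate_chipchip()] uses the
#' decile to scale each gene's exon effect, so marking follows expression
#' monotonically.
#'
#' @param config A [sim_config()].
#' @param annotation A `sim_annotation`.
#' @return A tibble (gene_id, value, decile).
#' @export
simulate_expression <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "sim_annotation"))
  set.seed(config$seed + 3L)
  genes <- annotation$models$genes
  n <- nrow(genes)
  value <- rlnorm(n, config$expression_meanlog, config$expression_sdlog)
  rank <- integer(n)
  rank[order(value, genes$gene_id)] <- seq_len(n)
  tibble(gene_id = genes$gene_id, value = value,
         decile = pmin(10L, 1L + as.integer(10 * (rank - 1) / n)))
}
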