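# small programmatic fixtures shared across test files

# two-transcript gene: exons A [0,100), B [500,650), C [1200,1400);
# transcript 2 skips B, so B is alternative with inclusion 0.5
toy_exons <- function(strand = "+") {
  tibble::tibble(
    gene_id = "g1",
    transcript_id = c("t1", "t1", "t1", "t2", "t2"),
    chrom = "chr1",
    start = c(0L, 500L, 1200L, 0L, 1200L),
    end = c(100L, 650L, 1400L, 100L, 1400L),
    strand = strand
  )
}

toy_models <- function(strand = "+") gene_models(toy_exons(strand))

# measurement table builder: one row per tile per replicate
make_measurements <- function(tile_id, chip, chip_bg = 50, input = 300,
                              input_bg = 100, replicate = 1,
                              flag = "ok", chrom = "chr1",
                              start = NULL, end = NULL) {
  n <- length(tile_id)
  if (is.null(start)) start <- (seq_len(n) - 1L) * 100L
  if (is.null(end)) end <- start + 100L
  tibble::tibble(
    tile_id = tile_id, chrom = chrom, start = start, end = end,
    replicate = replicate,
    chip = chip, chip_bg = chip_bg, input = input, input_bg = input_bg,
    flag = flag
  )
}

# a ratio-state track straight from values
make_track <- function(tile_id, value, state = "ratio",
                       assay = "histone_mod") {
  tile_track(tibble::tibble(tile_id = tile_id, value = value),
             state = state, assay = assay)
}

# simulation config used by several stats tests: big exons so every
# feature holds several tiles
recovery_config <- function(seed, ...) {
  args <- list(
    seed = seed, n_genes = 100,
    exon_count = c(4, 8),
    exon_len_meanlog = log(700), exon_len_sdlog = 0.2,
    intron_len_meanlog = log(1500), intron_len_sdlog = 0.3,
    transcripts = c(1, 1), tile_length = 100,
    noise_sd = 0.3, n_replicates = 3
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# full preprocessing of a simulated dataset: one simulation, both the raw
# and the histone-density/IgG-corrected z tracks
run_synthetic_chain <- function(cfg, normalized = TRUE) {
  ann <- simulate_annotation(cfg)
  sim <- simulate_chipchip(cfg, ann)
  density <- histone_density_track(
    composite_ratio_track(sim$measurements$h2b, "histone_density"),
    composite_ratio_track(sim$measurements$h3, "histone_density")
  )
  igg <- composite_ratio_track(sim$measurements$igg, "igg_control")
  track_raw <- preprocess_assay(sim$measurements$mod)
  track_norm <- if (normalized) {
    preprocess_assay(sim$measurements$mod, density = density, igg = igg)
  } else {
    NULL
  }
  models <- filter_genes(ann$models, relaxed = TRUE)
  assignment <- assign_tiles(sim$tiles, models)
  list(annotation = ann, sim = sim,
       track = if (normalized) track_norm else track_raw,
       track_raw = track_raw, track_norm = track_norm,
       models = models, assignment = assignment,
       density = density, igg = igg)
}

# delta (canonical exon mean - intron mean) in log2 units for a z track
delta_log2 <- function(track, assignment) {
  cm <- class_means(track, assignment)
  cm$delta$delta_z * track_sd(track)
}
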