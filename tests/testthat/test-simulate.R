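test_that("simulated annotations respect configured structure and determinism", {
  cfg <- sim_config(seed = 5, n_genes = 8, exon_count = c(3, 6),
                    transcripts = c(2, 4))
  ann <- simulate_annotation(cfg)
  g <- ann$models$genes
  expect_equal(nrow(g), 8)
  expect_true(all(g$n_exons >= 3 & g$n_exons <= 6))
  expect_setequal(unique(g$strand), c("+", "-"))
  # alternative exons have inclusion strictly between 0 and 1
  alt <- ann$models$features[ann$models$features$type == "alternative_exon", ]
  expect_true(all(alt$inclusion > 0 & alt$inclusion < 1))

  # single-transcript genes have only canonical exons
  cfg1 <- sim_config(seed = 6, n_genes = 3, transcripts = c(1, 1))
  ann1 <- simulate_annotation(cfg1)
  expect_equal(sum(ann1$models$features$type == "alternative_exon"), 0)

  # same seed -> byte-identical GFF
  f1 <- withr::local_tempfile(fileext = ".gff3")
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(simulate_annotation(cfg), f1)
  write_gff3(simulate_annotation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(sim_config(exon_count = c(5, 3)), "infeasible")
})

test_that("annotation round-trips exactly through GFF3", {
  cfg <- sim_config(seed = 9, n_genes = 6, transcripts = c(2, 3))
  ann <- simulate_annotation(cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- read_annotation(path)
  orig <- dplyr::arrange(ann$exons, gene_id, transcript_id, start)
  back <- dplyr::arrange(back, gene_id, transcript_id, start)
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_equal(back$strand, orig$strand)
  expect_equal(back$transcript_id, orig$transcript_id)
  # derived models identical
  gm <- gene_models(back)
  expect_equal(gm$features$type, ann$models$features$type)
  expect_equal(gm$features$inclusion, ann$models$features$inclusion)
})

test_that("zero-noise measurements recover planted effects exactly through the chain", {
  cfg <- recovery_config(13, n_genes = 20, exon_effect = 1, noise_sd = 0,
                         n_replicates = 1)
  out <- run_synthetic_chain(cfg)
  d <- delta_log2(out$track, out$assignment)
  expect_equal(d, 1.0, tolerance = 1e-12)
  # z-score invariant holds to 1e-9 relative
  expect_equal(median(out$track$value, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(out$track$value, na.rm = TRUE), 1, tolerance = 1e-9)
})

test_that("a pure density confound shows up raw and vanishes after histone normalization", {
  # zero noise: work on log2 composites directly (the corrected track is
  # exactly constant, which is the point)
  cfg <- recovery_config(14, n_genes = 30, exon_effect = 0,
                         density_exon_mult = 1.5, noise_sd = 0,
                         n_replicates = 1)
  ann <- simulate_annotation(cfg)
  sim <- simulate_chipchip(cfg, ann)
  comp <- composite_ratio_track(sim$measurements$mod)
  density <- histone_density_track(
    composite_ratio_track(sim$measurements$h2b),
    composite_ratio_track(sim$measurements$h3)
  )
  corrected <- normalize_by_track(comp, density)
  asn <- assign_tiles(sim$tiles, filter_genes(ann$models, relaxed = TRUE))
  log2_delta <- function(track) {
    d <- dplyr::inner_join(asn, track, by = "tile_id")
    mean(log2(d$value[d$type == "canonical_exon"])) -
      mean(log2(d$value[d$type == "intron"]))
  }
  expect_equal(log2_delta(comp), log2(1.5), tolerance = 1e-12)
  expect_equal(log2_delta(corrected), 0, tolerance = 1e-12)
})

test_that("all-zero effects at zero noise give a degenerate constant track", {
  cfg <- sim_config(seed = 15, n_genes = 5, noise_sd = 0, n_replicates = 1)
  ann <- simulate_annotation(cfg)
  sim <- simulate_chipchip(cfg, ann)
  expect_error(preprocess_assay(sim$measurements$mod), "degenerate track")
})

test_that("simulated reads follow the configured occupancy with exact counts", {
  cfg <- recovery_config(16, n_genes = 10)
  ann <- simulate_annotation(cfg)
  reads <- simulate_reads(cfg, ann, n_reads = 2000)
  expect_equal(nrow(reads), 2000)
  expect_true(all(reads$end - reads$start == 36))
  # fixed seed -> identical output
  expect_identical(as.data.frame(simulate_reads(cfg, ann, n_reads = 2000)),
                   as.data.frame(reads))

  # zero intron occupancy -> no read starts inside introns
  reads0 <- simulate_reads(cfg, ann, n_reads = 500,
                           weights = list(canonical_exon = 1,
                                          alternative_exon = 1,
                                          intron = 0, intergenic = 0))
  introns <- ann$models$features[ann$models$features$type == "intron", ]
  ir <- IRanges::IRanges(introns$start + 1L, introns$end)
  hits <- IRanges::overlapsAny(IRanges::IRanges(reads0$start + 1L,
                                                reads0$start + 1L), ir)
  expect_equal(sum(hits), 0)

  # uniform occupancy: per-bin counts match the mean within 3 SE
  reads_u <- simulate_reads(cfg, ann, n_reads = 5000,
                            weights = list(canonical_exon = 1,
                                           alternative_exon = 1,
                                           intron = 1, intergenic = 1))
  bt_u <- bin_reads(reads_u, bin_size = 200)
  counts <- bin_track_values(bt_u)$value
  lambda <- mean(counts)
  expect_lt(abs(lambda - 5000 / length(counts)), 1e-9)
  expect_lt(max(abs(counts - lambda)) / sqrt(lambda), 6)
})

test_that("expression simulation is decile-consistent and decoupled by default", {
  cfg <- sim_config(seed = 17, n_genes = 40)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  expect_equal(nrow(expr), 40)
  expect_equal(as.integer(table(expr$decile)), rep(4L, 10))
  expect_true(all(tapply(expr$value, expr$decile, max) ==
                    cummax(tapply(expr$value, expr$decile, max))))
  # coupling off: truth log2 identical across deciles
  sim <- simulate_chipchip(cfg, ann, expression = expr)
  expect_equal(length(unique(sim$truth$true_log2)), 1)
})

test_that("measurement tables round-trip through TSV", {
  cfg <- sim_config(seed = 18, n_genes = 3, n_replicates = 2)
  ann <- simulate_annotation(cfg)
  sim <- simulate_chipchip(cfg, ann)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measurements(sim$measurements$mod, path)
  back <- read_measurements(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$measurements$mod),
               tolerance = 1e-12)
})

test_that("the replicate-noise contract matches s/sqrt(n) for class means", {
  # single replicate, noise SD 0.3: SE of the exon-mean in log2 units
  # should match 0.3 / sqrt(n_exon_tiles) within 20%
  runs <- purrr::map_dfr(1:100, function(i) {
    cfg <- recovery_config(1000 + i, n_genes = 30, exon_effect = 0.5,
                           n_replicates = 1)
    ann <- simulate_annotation(cfg)
    sim <- simulate_chipchip(cfg, ann)
    z <- preprocess_assay(sim$measurements$mod)
    asn <- assign_tiles(sim$tiles, filter_genes(ann$models, relaxed = TRUE))
    s <- class_means(z, asn)$summary
    tibble::tibble(
      m = s$mean_z[s$type == "canonical_exon"] * track_sd(z),
      n = s$n[s$type == "canonical_exon"]
    )
  })
  se_obs <- sd(runs$m)
  se_pred <- 0.3 / sqrt(mean(runs$n))
  expect_lt(abs(se_obs - se_pred) / se_pred, 0.2)
})
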