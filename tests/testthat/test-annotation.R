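test_that("exons shared by all transcripts are canonical, others alternative", {
  gm <- toy_models()
  ex <- gm$features[gm$features$type != "intron", ]
  expect_equal(nrow(ex), 3)
  expect_equal(ex$type[ex$start == 0], "canonical_exon")
  expect_equal(ex$type[ex$start == 1200], "canonical_exon")
  expect_equal(ex$type[ex$start == 500], "alternative_exon")
  expect_equal(ex$inclusion, c(1, 0.5, 1))

  # single transcript: everything canonical with inclusion 1
  one <- classify_exons(tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "chr1",
    start = c(0L, 200L), end = c(100L, 300L), strand = "+"
  ))
  expect_equal(one$type, c("canonical_exon", "canonical_exon"))
  expect_equal(one$inclusion, c(1, 1))

  expect_error(classify_exons(toy_exons()[0, ]), "no transcripts")
})

test_that("partial canonical/alternative overlaps become excluded zones", {
  # [100,300) in both transcripts; [100,400) only in t2:
  # overlap bases [100,300) excluded, [300,400) usable alternative bases
  ex <- tibble::tibble(
    gene_id = "g", transcript_id = c("t1", "t2"), chrom = "chr1",
    start = c(100L, 100L), end = c(300L, 400L), strand = "+"
  )
  gm <- gene_models(ex)
  expect_equal(nrow(gm$excluded), 1)
  expect_equal(gm$excluded$start, 100)
  expect_equal(gm$excluded$end, 300)

  # a tile midpoint inside the excluded zone is unassigned; one in the
  # alternative-only stretch is assigned to the alternative exon
  tiles <- tibble::tibble(
    tile_id = c("a", "b"), chrom = "chr1",
    start = c(150L, 320L), end = c(250L, 380L)
  )
  asn <- assign_tiles(tiles, gm)
  expect_false("a" %in% asn$tile_id)
  expect_equal(asn$type[asn$tile_id == "b"], "alternative_exon")
})

test_that("introns are the gaps in the merged exon union, strand-aware ordinals", {
  gm <- toy_models()
  introns <- gm$features[gm$features$type == "intron", ]
  expect_equal(introns$start, c(100, 650))
  expect_equal(introns$end, c(500, 1200))
  expect_equal(introns$ordinal, c(1, 2))

  # minus strand: ordinal 1 is the 3'-most gap in genome coordinates
  gm_m <- toy_models("-")
  introns_m <- gm_m$features[gm_m$features$type == "intron", ]
  expect_equal(introns_m$ordinal[introns_m$start == 650], 1)
  expect_equal(introns_m$ordinal[introns_m$start == 100], 2)

  # single-exon gene has no introns
  single <- gene_models(tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "chr1",
    start = 0L, end = 100L, strand = "+"
  ))
  expect_equal(sum(single$features$type == "intron"), 0)
})

test_that("gene filters apply span and exon-count thresholds", {
  ex <- dplyr::bind_rows(
    tibble::tibble(gene_id = "big", transcript_id = "t", chrom = "chr1",
                   start = c(0L, 2900L, 5900L), end = c(100L, 3000L, 6000L),
                   strand = "+"),
    tibble::tibble(gene_id = "short", transcript_id = "t", chrom = "chr1",
                   start = 10000L + c(0L, 500L, 1000L, 1500L, 1900L),
                   end = 10000L + c(100L, 600L, 1100L, 1600L, 1999L),
                   strand = "+"),
    tibble::tibble(gene_id = "fewexon", transcript_id = "t", chrom = "chr1",
                   start = c(20000L, 29000L), end = c(20100L, 29100L),
                   strand = "+")
  )
  gm <- gene_models(ex)
  # span exactly 6000 with 3 exons is kept; 5999-span/10-exon genes drop
  kept <- filter_genes(gm)
  expect_equal(kept$genes$gene_id, "big")
  # relaxed mode keeps any 3-exon gene regardless of span
  relaxed <- filter_genes(gm, relaxed = TRUE)
  expect_setequal(relaxed$genes$gene_id, c("big", "short"))
})

test_that("tiles are assigned by midpoint with 5'/body split at 25%", {
  ex <- tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "chr1",
    start = c(0L, 200L, 900L), end = c(100L, 400L, 1000L), strand = "+"
  )
  gm <- gene_models(ex)
  tiles <- tibble::tibble(
    tile_id = c("inexon", "spanning", "in5", "inbody", "outside", "offchrom"),
    chrom = c(rep("chr1", 5), "chrX"),
    start = c(220L, 180L, 150L, 420L, 5000L, 0L),
    end = c(270L, 230L, 250L, 470L, 5100L, 100L)
  )
  expect_warning(asn <- assign_tiles(tiles, gm), "unassigned")
  # midpoint 245 inside exon [200,400)
  expect_equal(asn$type[asn$tile_id == "inexon"], "canonical_exon")
  # tile spanning the exon boundary: midpoint 205 -> exon
  expect_equal(asn$type[asn$tile_id == "spanning"], "canonical_exon")
  # gene span 1000: 5' cut at 250
  expect_equal(asn$region[asn$tile_id == "in5"], "five_prime")
  expect_equal(asn$region[asn$tile_id == "inbody"], "body")
  expect_false("outside" %in% asn$tile_id)
  expect_false("offchrom" %in% asn$tile_id)
})

test_that("classification and assignment are invariant under strand reflection", {
  # reflect all coordinates around 2000 and flip strand
  ex <- toy_exons("+")
  refl <- ex
  refl$start <- 2000L - ex$end
  refl$end <- 2000L - ex$start
  refl$strand <- "-"
  gm_f <- gene_models(ex)
  gm_r <- gene_models(refl)

  f <- gm_f$features[order(gm_f$features$ordinal, gm_f$features$type), ]
  r <- gm_r$features[order(gm_r$features$ordinal, gm_r$features$type), ]
  expect_equal(f$type, r$type)
  expect_equal(f$ordinal, r$ordinal)
  expect_equal(f$inclusion, r$inclusion)
  # mirrored tiles land in the mirrored features with the same ordinal
  tiles <- tibble::tibble(tile_id = "x", chrom = "chr1",
                          start = 520L, end = 570L)
  tiles_r <- tibble::tibble(tile_id = "x", chrom = "chr1",
                            start = 2000L - 570L, end = 2000L - 520L)
  a_f <- assign_tiles(tiles, gm_f)
  a_r <- assign_tiles(tiles_r, gm_r)
  expect_equal(a_f$type, a_r$type)
  expect_equal(a_f$ordinal, a_r$ordinal)
  expect_equal(a_f$region, a_r$region)
})

test_that("assignment is deterministic, idempotent and one-feature-per-tile", {
  cfg <- sim_config(seed = 11, n_genes = 10, transcripts = c(2, 3))
  ann <- simulate_annotation(cfg)
  tiles <- tile_layout(ann)
  a1 <- assign_tiles(tiles, ann$models)
  a2 <- assign_tiles(tiles, ann$models)
  expect_identical(a1, a2)
  expect_equal(anyDuplicated(a1$tile_id), 0L)
  # inclusion_fraction invariant under transcript reordering
  ex <- ann$exons[sample.int(nrow(ann$exons)), ]
  gm2 <- gene_models(ex)
  f1 <- dplyr::arrange(ann$models$features, gene_id, start, type)
  f2 <- dplyr::arrange(gm2$features, gene_id, start, type)
  expect_equal(f1$inclusion, f2$inclusion)
})
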