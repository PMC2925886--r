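#' Run the exon-intron marking analysis end to end
#'
#' Orchestrates the stages: simulate (optional) or load inputs, preprocess
#' the ChIP-chip measurements (with and without histone-density/IgG
#' correction), assign tiles to gene features, call expression states,
#' build metaprofiles and class means, run the coordinate-randomization
#' bootstrap and adjacent-pair t-tests, and write report tables. Every
#' output table carries the seed; the Z-score tracks carry their
#' normalization audit record.
#'
#' The configuration is a named list, or a path to a YAML or JSON file
#' with the same structure:
#' \preformatted{
#' seed: 1
#' simulate:            # optional; omit to analyze provided inputs
#'   n_genes: 50
#'   exon_effect: 0.5
#' inputs:              # optional; paths to existing files
#'   annotation: genes.gff3
#'   measurements: {mod: mod.tsv, h2b: h2b.tsv, h3: h3.tsv, igg: igg.tsv}
#'   expression: expr.tsv
#' analysis:
#'   R: 100
#'   alpha: 0.05
#'   mode: five_prime
#'   min_span: 6000
#'   min_exons: 3
#'   relaxed: false
#' output_dir: out
#' }
#'
#' @param config A named list, or path to a YAML/JSON config file.
#' @param simulate_only If `TRUE`, emit the synthetic fixtures into
#'   `output_dir` and stop before any analysis.
#' @return A named list of results: `annotation`, `tracks` (raw and
#'   normalized Z-score tracks), `assignment`, `profile`, `class_summary`,
#'   `bootstrap`, `ttests`, `expression`, `seed`. Tables are also written
#'   to `output_dir` when set.
#' @export
run_pipeline <- function(config, simulate_only = FALSE) {
  cfg <- load_run_config(config)
  seed <- cfg$seed %||% 1L
  ana <- cfg$analysis %||% list()
  outdir <- cfg$output_dir
  if (length(outdir) != 1 || !nzchar(outdir)) outdir <- NULL

  # validate the manifest before any computation
  if (!is.null(cfg$inputs)) {
    paths <- unlist(cfg$inputs, use.names = TRUE)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      abort(paste0("missing input file(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    annotation <- simulate_annotation(scfg)
    expression <- simulate_expression(scfg, annotation)
    sim <- simulate_chipchip(scfg, annotation, expression = expression)
    tiles <- sim$tiles
    measurements <- sim$measurements
    if (!is.null(outdir)) {
      write_gff3(annotation, file.path(outdir, "annotation.gff3"))
      for (nm in names(measurements)) {
        write_measurements(measurements[[nm]],
                           file.path(outdir, paste0(nm, "_measurements.tsv")))
      }
      write_expression(expression, file.path(outdir, "expression.tsv"))
      utils::write.table(sim$truth, file.path(outdir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (simulate_only) {
      return(invisible(list(annotation = annotation, tiles = tiles,
                            measurements = measurements,
                            expression = expression, seed = seed)))
    }
  } else {
    if (is.null(cfg$inputs)) abort("config needs a simulate or inputs block")
    exons <- read_annotation(cfg$inputs$annotation)
    annotation <- list(exons = exons, models = gene_models(exons))
    class(annotation) <- "sim_annotation"
    measurements <- lapply(cfg$inputs$measurements, read_measurements)
    m <- measurements$mod
    tiles <- m %>%
      distinct(.data$tile_id, .data$chrom, .data$start, .data$end)
    expression <- if (!is.null(cfg$inputs$expression)) {
      read_expression(cfg$inputs$expression)
    } else {
      NULL
    }
  }

  # preprocess: raw chain and histone-density/IgG-corrected chain
  density <- if (!is.null(measurements$h2b) && !is.null(measurements$h3)) {
    histone_density_track(composite_ratio_track(measurements$h2b, "histone_density"),
                          composite_ratio_track(measurements$h3, "histone_density"))
  } else {
    NULL
  }
  igg <- if (!is.null(measurements$igg)) {
    composite_ratio_track(measurements$igg, "igg_control")
  } else {
    NULL
  }
  track_raw <- preprocess_assay(measurements$mod)
  track_norm <- preprocess_assay(measurements$mod, density = density,
                                 igg = igg)

  models <- filter_genes(annotation$models,
                         min_span = ana$min_span %||% 6000,
                         min_exons = ana$min_exons %||% 3,
                         relaxed = isTRUE(ana$relaxed))
  assignment <- assign_tiles(tiles, models)

  expr_calls <- if (!is.null(expression) && nrow(expression) >= 4) {
    call_on_off(expression)
  } else {
    NULL
  }
  mode <- ana$mode %||% "five_prime"
  gene_set <- if (!is.null(ana$expression_status) && !is.null(expr_calls)) {
    expr_calls$gene_id[expr_calls$status == ana$expression_status]
  } else {
    NULL
  }

  profile <- exon_intron_profile(track_norm, assignment, models,
                                 mode = mode, gene_set = gene_set)
  summary <- class_means(track_norm, assignment, gene_set = gene_set,
                         region_split = isTRUE(ana$region_split))
  boot <- bootstrap_pvalues(track_norm, assignment, gene_set = gene_set,
                            R = ana$R %||% 100, seed = seed)
  ttests <- adjacent_pair_ttests(track_norm, assignment, models,
                                 gene_set = gene_set, mode = mode)

  results <- list(
    annotation = annotation, tiles = tiles,
    tracks = list(raw = track_raw, normalized = track_norm),
    assignment = assignment, profile = profile, class_summary = summary,
    bootstrap = boot, ttests = ttests, expression = expr_calls,
    seed = seed
  )
  if (!is.null(outdir)) report(results, outdir)
  results
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    abort("config must be a list or a path to a YAML/JSON file")
  }
}

#' Write report tables for a pipeline run
#'
#' One tab-delimited table per analysis: the consensus profile, class
#' means with the signed exon-intron delta Z (rendered with an explicit
#' +/-), bootstrap p-values, adjacent-pair t-tests, and (when present)
#' bias-call concordance. Empty results produce tables with headers only.
#' Every table carries a `# seed:` comment line.
#'
#' @param results Result list from [run_pipeline()], possibly partial.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- results$seed %||% NA_integer_
  wt <- function(d, file) {
    p <- file.path(dir, file)
    con <- file(p, "w")
    writeLines(paste0("# seed: ", seed), con)
    close(con)
    suppressWarnings(utils::write.table(
      d, p, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE
    ))
    p
  }
  prof <- if (!is.null(results$profile)) as_tibble(results$profile) else
    tibble(slot = character(), feature = character(), ordinal = integer(),
           mean_z = double(), n = integer(), ci = double())
  wt(prof, "profile.tsv")

  if (!is.null(results$class_summary)) {
    s <- results$class_summary$summary
    d <- results$class_summary$delta %>%
      mutate(delta_z = sprintf("%+.4f", .data$delta_z))
  } else {
    s <- tibble(type = character(), region = character(), mean_z = double(),
                n = integer(), ci = double())
    d <- tibble(region = character(), delta_z = character())
  }
  wt(s, "class_means.tsv")
  wt(d, "delta_z.tsv")

  boot <- if (!is.null(results$bootstrap)) tidy(results$bootstrap) else
    tibble(class = character(), observed = double(), rand_mean = double(),
           rand_sd = double(), p_empirical = double(),
           p_parametric = double(), n_tiles = integer())
  wt(boot, "bootstrap.tsv")

  tt <- if (!is.null(results$ttests)) tidy(results$ttests) else
    tibble(pair = character(), exon_ordinal = integer(),
           intron_ordinal = integer(), n_exon = integer(),
           n_intron = integer(), t = double(), df = double(), p = double())
  wt(tt, "ttests.tsv")

  if (!is.null(results$concordance)) {
    wt(results$concordance, "concordance.tsv")
  }
  if (!is.null(results$expression)) {
    write_expression(results$expression, file.path(dir, "expression_calls.tsv"))
  }
  invisible(dir)
}
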