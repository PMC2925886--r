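#' Coordinate-randomization of a track
#'
#' Builds randomized datasets for the bootstrap null by permuting the
#' observed values uniformly at random over the observed tile coordinates:
#' the geometry (tile positions, and hence the feature annotation) stays
#' fixed while the values move, which is equivalent, for tile-mean
#' statistics, to assigning the datapoints to random genomic coordinates.
#'
#' @param track A `tile_track` with at least 2 non-missing values.
#' @param R Number of randomizations (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of `R` `tile_track`s, each a permutation of the input
#'   values over the same tile ids.
#' @export
randomize_track <- function(track, R = 100, seed = NULL) {
  if (R < 1) abort("R must be at least 1")
  v <- track_values(track)
  if (sum(!is.na(v$value)) < 2) abort("need at least 2 non-missing tiles")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(R), function(r) {
    tile_track(tibble(tile_id = v$tile_id, value = sample(v$value)),
               state = attr(track, "state") %||% "zscore",
               assay = attr(track, "assay") %||% "histone_mod")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap p-values for feature-class means
#'
#' Compares the observed mean of each feature class (canonical exons,
#' alternative exons, introns) against the distribution of means obtained
#' from `R` coordinate-randomized datasets, with the feature annotation
#' held fixed. Two p-values are reported per class: an empirical p,
#' `(1 + #[randomized at least as extreme]) / (R + 1)` (two-sided by
#' absolute deviation from the randomized mean, or one-sided on request),
#' and a parametric p from the normal approximation
#' `z = (observed - mean_rand) / sd_rand` — the empirical p is bounded
#' below by `1/(R+1)`, so very small significance levels are only
#' expressible parametrically. The exon-intron bias delta Z
#' (canonical-exon mean minus intron mean) is tested the same way.
#'
#' @param track A `tile_track` (Z-scores for ChIP-chip, counts for
#'   ChIP-seq bins). All tiles of the track form the randomization domain.
#' @param assignment Tile assignment from [assign_tiles()]/[assign_bins()].
#' @param gene_set Optional gene ids to restrict the assignment to.
#' @param R Number of randomizations (default 100).
#' @param seed Optional integer seed.
#' @param sided `"two"` (default) or `"one"` (one-sided toward the
#'   observed direction).
#' @param classes Feature classes to test.
#' @return A `bootstrap_result`: list with `classes` (tibble: class,
#'   observed, rand_mean, rand_sd, p_empirical, p_parametric, n_tiles),
#'   `delta` (same columns for delta Z), `R`, `seed`, `sided`.
#' @export
bootstrap_pvalues <- function(track, assignment, gene_set = NULL, R = 100,
                              seed = NULL, sided = c("two", "one"),
                              classes = c("canonical_exon",
                                          "alternative_exon", "intron")) {
  sided <- match.arg(sided)
  if (R < 1) abort("R must be at least 1")
  v <- track_values(track)
  keep <- !is.na(v$value)
  if (sum(keep) < 2) abort("need at least 2 non-missing tiles")
  v <- v[keep, ]
  asn <- as_tibble(assignment)
  if (!is.null(gene_set)) asn <- asn %>% filter(.data$gene_id %in% gene_set)

  idx <- lapply(classes, function(cl) {
    which(v$tile_id %in% asn$tile_id[asn$type == cl])
  })
  names(idx) <- classes
  have <- vapply(idx, length, integer(1)) > 0

  if (!is.null(seed)) set.seed(seed)
  vals <- v$value
  obs <- vapply(classes, function(cl) {
    if (have[[cl]]) mean(vals[idx[[cl]]]) else NA_real_
  }, numeric(1))

  rand <- matrix(NA_real_, nrow = R, ncol = length(classes),
                 dimnames = list(NULL, classes))
  for (r in seq_len(R)) {
    p <- sample(vals)
    for (cl in classes[have]) rand[r, cl] <- mean(p[idx[[cl]]])
  }

  class_tbl <- purrr::map_dfr(classes, function(cl) {
    summarize_bootstrap(cl, obs[[cl]], rand[, cl], R, sided,
                        length(idx[[cl]]))
  })
  d_obs <- obs[["canonical_exon"]] - obs[["intron"]]
  d_rand <- rand[, "canonical_exon"] - rand[, "intron"]
  delta_tbl <- summarize_bootstrap("delta_z", d_obs, d_rand, R, sided,
                                   length(idx[["canonical_exon"]]) +
                                     length(idx[["intron"]]))
  structure(
    list(classes = class_tbl, delta = delta_tbl, R = R, seed = seed,
         sided = sided, randomized = rand),
    class = "bootstrap_result"
  )
}

summarize_bootstrap <- function(label, obs, rand, R, sided, n_tiles) {
  if (is.na(obs) || all(is.na(rand))) {
    return(tibble(class = label, observed = obs, rand_mean = NA_real_,
                  rand_sd = NA_real_, p_empirical = NA_real_,
                  p_parametric = NA_real_, n_tiles = n_tiles))
  }
  m <- mean(rand)
  s <- sd(rand)
  if (sided == "two") {
    p_emp <- (1 + sum(abs(rand - m) >= abs(obs - m))) / (R + 1)
    p_par <- if (s > 0) 2 * pnorm(-abs((obs - m) / s)) else
      as.numeric(obs == m)
  } else {
    # one-sided toward the observed direction
    if (obs >= m) {
      p_emp <- (1 + sum(rand >= obs)) / (R + 1)
      p_par <- if (s > 0) pnorm((obs - m) / s, lower.tail = FALSE) else
        as.numeric(obs <= m)
    } else {
      p_emp <- (1 + sum(rand <= obs)) / (R + 1)
      p_par <- if (s > 0) pnorm((obs - m) / s) else as.numeric(obs >= m)
    }
  }
  tibble(class = label, observed = obs, rand_mean = m, rand_sd = s,
         p_empirical = p_emp, p_parametric = p_par, n_tiles = n_tiles)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> R =", x$R, ", ", x$sided, "-sided\n", sep = "")
  print(bind_rows(x$classes, x$delta))
  invisible(x)
}

#' Welch t-tests between adjacent exon-intron pairs
#'
#' Two-tailed t-tests comparing tile values of each canonical exon slot
#' against the preceding intron slot across the consensus gene structure:
#' exon k versus intron k-1 for k = 2..10 in 5' mode (9 pairs), and the
#' last four exon/preceding-intron pairs in 3' mode. Pairs with fewer than
#' 2 tiles on either side or zero pooled variance are skipped with a
#' warning. The median p over the tested pairs is the headline statistic.
#'
#' @inheritParams bootstrap_pvalues
#' @param models Needed in `three_prime` mode for 3'-counted ordinals.
#' @param mode `"five_prime"` (default) or `"three_prime"`.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A `pair_test`: tibble (pair, exon_ordinal, intron_ordinal,
#'   n_exon, n_intron, t, df, p) with attributes `median_p` and `mode`.
#' @export
adjacent_pair_ttests <- function(track, assignment, models = NULL,
                                 gene_set = NULL,
                                 mode = c("five_prime", "three_prime"),
                                 var_equal = FALSE) {
  mode <- match.arg(mode)
  asn <- joined_assignment(track, assignment, gene_set)
  asn <- asn %>% filter(.data$type %in% c("canonical_exon", "intron"))
  if (mode == "three_prime") {
    if (is.null(models)) abort("three_prime mode needs the gene_models object")
    asn <- add_rev_ordinals(asn, models)
    asn$use_ordinal <- asn$rev_ordinal
    pairs <- tibble(exon_ordinal = 1:4, intron_ordinal = 1:4)
    pair_label <- paste0("exon_last", c("", paste0("-", 1:3)),
                         "_vs_intron")
  } else {
    asn$use_ordinal <- asn$ordinal
    pairs <- tibble(exon_ordinal = 2:10, intron_ordinal = 1:9)
    pair_label <- paste0("exon", 2:10, "_vs_intron", 1:9)
  }

  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ek <- pairs$exon_ordinal[i]
    ik <- pairs$intron_ordinal[i]
    x <- asn$value[asn$type == "canonical_exon" & asn$use_ordinal == ek]
    y <- asn$value[asn$type == "intron" & asn$use_ordinal == ik]
    base <- tibble(pair = pair_label[i], exon_ordinal = ek,
                   intron_ordinal = ik, n_exon = length(x),
                   n_intron = length(y))
    if (length(x) < 2 || length(y) < 2) {
      # genes simply don't extend this far: skip silently
      return(base %>% mutate(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      warn(paste0("pair ", pair_label[i], " skipped (degenerate variance)"))
      return(base %>% mutate(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- t.test(x, y, var.equal = var_equal)
    base %>% mutate(t = unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value)
  })
  structure(rows,
            median_p = median(rows$p, na.rm = TRUE), mode = mode,
            class = c("pair_test", class(tibble())))
}

#' @rdname adjacent_pair_ttests
#' @param x A `pair_test`.
#' @export
median_pair_p <- function(x) attr(x, "median_p")

#' Exon/intron bias calls and cross-dataset concordance
#'
#' Turns per-dataset bias summaries into categorical calls: `exon_bias`
#' when delta Z > 0 with p below `alpha`, `intron_bias` when delta Z < 0
#' with p below `alpha`, otherwise `none`. Concordance between two
#' datasets is the number of marks with identical non-`none` calls.
#'
#' @param summaries A data frame with columns `dataset`, `mark` (or any
#'   grouping key), `delta_z` and `p`.
#' @param alpha Significance threshold (default 0.05).
#' @return A list with `calls` (the input plus a `call` column) and
#'   `concordance` (tibble: dataset_a, dataset_b, n_agree).
#' @export
bias_call_and_concordance <- function(summaries, alpha = 0.05) {
  s <- as_tibble(summaries)
  req <- c("dataset", "mark", "delta_z", "p")
  miss <- setdiff(req, names(s))
  if (length(miss) > 0) {
    abort(paste0("summaries are missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  calls <- s %>%
    mutate(call = case_when(
      .data$p < alpha & .data$delta_z > 0 ~ "exon_bias",
      .data$p < alpha & .data$delta_z < 0 ~ "intron_bias",
      TRUE ~ "none"
    ))
  ds <- sort(unique(calls$dataset))
  conc <- purrr::map_dfr(seq_along(ds), function(i) {
    purrr::map_dfr(seq_along(ds), function(j) {
      if (j <= i) return(tibble())
      a <- calls %>% filter(.data$dataset == ds[i]) %>%
        select("mark", call_a = "call")
      b <- calls %>% filter(.data$dataset == ds[j]) %>%
        select("mark", call_b = "call")
      ab <- inner_join(a, b, by = "mark")
      tibble(dataset_a = ds[i], dataset_b = ds[j],
             n_agree = sum(ab$call_a == ab$call_b & ab$call_a != "none"))
    })
  })
  list(calls = calls, concordance = conc)
}
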