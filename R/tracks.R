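#' Tile tracks
#'
#' A tile track holds one value per array tile (or genomic bin) for one
#' assay, together with its normalization state and an append-only audit
#' record of the steps that produced it. Missing values stay as `NA` rows so
#' that tracks remain aligned on the same tile universe throughout the
#' chain.
#'
#' @param values A data frame with columns `tile_id` and `value`.
#' @param state One of `"ratio"`, `"composite"`, `"normalized"`,
#'   `"zscore"`, `"counts"`.
#' @param assay Assay kind, e.g. `"histone_mod"`, `"histone_density"`,
#'   `"pol2"`, `"faire"`, `"igg_control"`, `"seq_chip"`, `"expression"`.
#' @param record A list of audit-step entries (see [track_record()]).
#' @return A tibble of class `tile_track` with attributes `state`, `assay`
#'   and `record`.
#' @export
tile_track <- function(values, state, assay = "histone_mod",
                       record = list()) {
  values <- as_tibble(values)[, c("tile_id", "value")]
  if (anyDuplicated(values$tile_id)) abort("tile_id values must be unique")
  structure(
    values,
    state = state, assay = assay, record = record,
    class = c("tile_track", class(tibble())))
}

#' @rdname tile_track
#' @param track A `tile_track`.
#' @export
track_state <- function(track) attr(track, "state")

#' @rdname tile_track
#' @export
track_record <- function(track) attr(track, "record")

#' @rdname tile_track
#' @details `track_sd()` returns the standard deviation recorded by the
#'   final Z-scoring step, i.e. the factor that converts the track's
#'   Z units back to log2 units (`log2 = Z * track_sd`). `NULL` if the
#'   track has not been Z-scored.
#' @export
track_sd <- function(track) {
  rec <- track_record(track)
  for (step in rev(rec)) {
    if (step$step == "to_zscores") return(step$params$sd)
  }
  NULL
}

# fast per-row median with NA handling; closed forms for the common
# replicate counts, generic fallback otherwise
row_medians <- function(mat) {
  k <- ncol(mat)
  if (k == 1) return(mat[, 1])
  complete <- rowSums(is.na(mat)) == 0
  med <- rep(NA_real_, nrow(mat))
  if (k == 2) {
    med <- rowMeans(mat, na.rm = TRUE)
    med[is.nan(med)] <- NA_real_
    return(med)
  }
  if (k == 3) {
    a <- mat[complete, 1]; b <- mat[complete, 2]; c_ <- mat[complete, 3]
    med[complete] <- pmax(pmin(a, b), pmin(pmax(a, b), c_))
  } else if (any(complete)) {
    med[complete] <- apply(mat[complete, , drop = FALSE], 1, median)
  }
  rest <- which(!complete)
  if (length(rest) > 0) {
    med[rest] <- apply(mat[rest, , drop = FALSE], 1, function(v) {
      if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
    })
  }
  med
}

record_step <- function(track, step, params = list()) {
  rec <- c(track_record(track), list(list(step = step, params = params)))
  attr(track, "record") <- rec
  track
}

set_state <- function(track, state) {
  attr(track, "state") <- state
  track
}

track_values <- function(track) {
  if (inherits(track, "tile_track")) return(track)
  as_tibble(track)[, c("tile_id", "value")]
}

#' Compute per-tile enrichment ratios for one replicate
#'
#' The enrichment ratio of a tile is the background-corrected ChIP signal
#' divided by the background-corrected input signal. Tiles flagged
#' `not_found`, with non-finite ratios, or with ratios at or below zero are
#' set missing. Ratios of duplicated spots (repeated `tile_id`) are averaged
#' before the surviving ratios are globally scaled to median 1.
#'
#' @param measurements A data frame for a single replicate with columns
#'   `tile_id`, `chip`, `chip_bg`, `input`, `input_bg` and optionally `flag`
#'   (`"ok"` or `"not_found"`) and `replicate`.
#' @param assay Assay label stored on the track.
#' @return A `tile_track` with `state = "ratio"`, median 1 over non-missing
#'   tiles.
#' @export
enrichment_ratio <- function(measurements, assay = "histone_mod") {
  m <- as_tibble(measurements)
  req <- c("tile_id", "chip", "chip_bg", "input", "input_bg")
  miss <- setdiff(req, names(m))
  if (length(miss) > 0) {
    abort(paste0("measurement table is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if ("replicate" %in% names(m) && n_distinct(m$replicate) > 1) {
    abort("enrichment_ratio() expects measurements for a single replicate; see composite_median()")
  }
  ok <- if ("flag" %in% names(m)) m$flag == "ok" else rep(TRUE, nrow(m))
  r <- (m$chip - m$chip_bg) / (m$input - m$input_bg)
  r[!ok] <- NA_real_
  r[!is.finite(r) | r <= 0] <- NA_real_

  if (anyDuplicated(m$tile_id)) {
    # average duplicated spots over their non-missing ratios
    has <- !is.na(r)
    sums <- rowsum(ifelse(has, r, 0), m$tile_id)
    ns <- rowsum(as.numeric(has), m$tile_id)
    value <- as.vector(sums / ns)
    value[as.vector(ns) == 0] <- NA_real_
    vals <- tibble(tile_id = rownames(sums), value = value)
  } else {
    vals <- tibble(tile_id = m$tile_id, value = r)
  }
  if (all(is.na(vals$value))) abort("empty track")
  med <- median(vals$value, na.rm = TRUE)
  vals$value <- vals$value / med
  track <- tile_track(vals, state = "ratio", assay = assay)
  record_step(track, "enrichment_ratio",
              list(assay = assay, median_scale = med))
}

#' Median composite across replicate tracks
#'
#' Per tile, the median across replicates with a non-missing value; tiles
#' missing in every replicate stay missing.
#'
#' @param tracks A list of `tile_track`s on the same tile set (typically
#'   per-replicate ratio tracks).
#' @return A `tile_track` with `state = "composite"`.
#' @export
composite_median <- function(tracks) {
  if (inherits(tracks, "tile_track")) tracks <- list(tracks)
  if (length(tracks) == 0) abort("no replicate tracks supplied")
  ids <- sort(tracks[[1]]$tile_id)
  for (t in tracks[-1]) {
    if (!identical(sort(t$tile_id), ids)) abort("mismatched tile sets across replicates")
  }
  mat <- vapply(tracks, function(t) t$value[order(t$tile_id)],
                numeric(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  med <- row_medians(mat)
  track <- tile_track(tibble(tile_id = ids, value = med),
                      state = "composite", assay = attr(tracks[[1]], "assay"),
                      record = track_record(tracks[[1]]))
  record_step(track, "composite_median", list(n_replicates = length(tracks)))
}

#' Tile-by-tile normalization against a reference track
#'
#' Divides a track by a denominator track tile by tile (e.g. a histone
#' modification composite by the combined H2B/H3 histone-density composite,
#' or by an IgG control composite). Tiles where the denominator is missing
#' or non-positive become missing. Calls chain, so a track can be corrected
#' for histone density and then for IgG.
#'
#' @param track A `tile_track` (ratio or composite state).
#' @param denominator A `tile_track` on the same tile universe.
#' @return A `tile_track` with `state = "normalized"`.
#' @export
normalize_by_track <- function(track, denominator) {
  a <- track_values(track)
  b <- track_values(denominator)
  if (!identical(sort(a$tile_id), sort(b$tile_id))) {
    abort("track and denominator are on different tile universes")
  }
  d <- b$value[match(a$tile_id, b$tile_id)]
  d[!is.na(d) & d <= 0] <- NA_real_
  out <- tile_track(
    tibble(tile_id = a$tile_id, value = a$value / d),
    state = "normalized", assay = attr(track, "assay"),
    record = track_record(track)
  )
  record_step(out, "normalize_by_track",
              list(denominator_assay = attr(denominator, "assay")))
}

#' Convert a ratio-scale track to log2 centred Z-scores
#'
#' Values are log2-transformed, centred on the median of the whole dataset,
#' and divided by the sample standard deviation of the centred values, so
#' the resulting track has median 0 and sample SD 1 over its non-missing
#' tiles.
#'
#' @param track A `tile_track` on ratio scale (positive values; non-positive
#'   values must already be missing).
#' @return A `tile_track` with `state = "zscore"`.
#' @export
to_zscores <- function(track) {
  v <- track_values(track)
  x <- v$value
  x[!is.na(x) & x <= 0] <- NA_real_
  if (sum(!is.na(x)) < 3) abort("need at least 3 non-missing positive values")
  l <- log2(x)
  centred <- l - median(l, na.rm = TRUE)
  s <- sd(centred, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort("degenerate track")
  out <- tile_track(
    tibble(tile_id = v$tile_id, value = centred / s),
    state = "zscore", assay = attr(track, "assay"),
    record = track_record(track)
  )
  record_step(out, "to_zscores", list(sd = s))
}

#' Combined histone-density track from H2B and H3
#'
#' The nucleosome-density reference used to correct modification tracks:
#' the per-tile mean of the H2B and H3 composite ratio tracks.
#'
#' @param h2b,h3 Composite ratio `tile_track`s for histones H2B and H3.
#' @return A `tile_track` with `assay = "histone_density"`.
#' @export
histone_density_track <- function(h2b, h3) {
  a <- track_values(h2b)
  b <- track_values(h3)
  if (!identical(sort(a$tile_id), sort(b$tile_id))) {
    abort("H2B and H3 tracks are on different tile universes")
  }
  bv <- b$value[match(a$tile_id, b$tile_id)]
  val <- rowMeans(cbind(a$value, bv), na.rm = TRUE)
  val[is.nan(val)] <- NA_real_
  out <- tile_track(tibble(tile_id = a$tile_id, value = val),
                    state = "composite", assay = "histone_density")
  record_step(out, "histone_density_track", list())
}

#' Run the standard ChIP-chip normalization chain for one assay
#'
#' Per-replicate enrichment ratios, replicate median composite, optional
#' histone-density then IgG correction, then log2 centred Z-scores. This is
#' the chain applied to every histone-modification, Pol II and FAIRE
#' dataset; the audit record on the returned track lists each step applied.
#'
#' @param measurements Measurement table with a `replicate` column covering
#'   one or more replicates (columns as in [enrichment_ratio()]).
#' @param density Optional histone-density `tile_track`
#'   (see [histone_density_track()]).
#' @param igg Optional IgG control composite `tile_track`.
#' @param assay Assay label.
#' @return A Z-score `tile_track`.
#' @export
preprocess_assay <- function(measurements, density = NULL, igg = NULL,
                             assay = "histone_mod") {
  m <- as_tibble(measurements)
  if (!"replicate" %in% names(m)) m$replicate <- 1L
  reps <- split(m, m$replicate)
  tracks <- lapply(reps, enrichment_ratio, assay = assay)
  comp <- composite_median(tracks)
  if (!is.null(density)) comp <- normalize_by_track(comp, density)
  if (!is.null(igg)) comp <- normalize_by_track(comp, igg)
  to_zscores(comp)
}

#' Composite ratio track from multi-replicate measurements
#'
#' Convenience wrapper: per-replicate [enrichment_ratio()] followed by
#' [composite_median()]. Used to build the histone-density and IgG
#' reference composites.
#'
#' @inheritParams preprocess_assay
#' @return A composite ratio `tile_track`.
#' @export
composite_ratio_track <- function(measurements, assay = "histone_mod") {
  m <- as_tibble(measurements)
  if (!"replicate" %in% names(m)) m$replicate <- 1L
  composite_median(lapply(split(m, m$replicate), enrichment_ratio,
                          assay = assay))
}
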