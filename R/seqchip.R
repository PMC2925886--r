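#' Normalize a sequential-ChIP experiment against its IgG-round control
#'
#' Sequential ChIP (two consecutive immunoprecipitations) is quantified
#' against a control in which the second round used pre-immune IgG. Both
#' datasets are background-corrected per channel, each replicate is scaled
#' so its median input equals 1 (so bioreplicates are averaged on a common
#' input scale), and replicates are averaged per tile. Scaling both datasets
#' to their median input signals also places the experimental and control
#' ChIP channels on a common scale; the corrected signal is then the
#' tile-wise difference experimental minus control;
#' non-positive corrected signals become missing rather than being clamped,
#' to avoid log2 degeneracy. The enrichment ratio is taken against the
#' normalized experimental input channel, median-centred, optionally
#' corrected for histone density and IgG, and Z-scored.
#'
#' @param seq_exp Measurement table for the sequential-ChIP experiment
#'   (columns as in [enrichment_ratio()], plus `replicate`).
#' @param seq_ctrl Measurement table for the sequential-ChIP control on the
#'   same tiles.
#' @param density Optional histone-density `tile_track`.
#' @param igg Optional IgG composite `tile_track`.
#' @return A Z-score `tile_track` with `assay = "seq_chip"`.
#' @export
seqchip_normalize <- function(seq_exp, seq_ctrl, density = NULL, igg = NULL) {
  e <- seqchip_channels(seq_exp)
  c_ <- seqchip_channels(seq_ctrl)
  if (!identical(sort(e$tile_id), sort(c_$tile_id))) {
    abort("experimental and control sequential datasets must share tiles")
  }
  c_ <- c_[match(e$tile_id, c_$tile_id), ]

  # both datasets are already on the common input-defined scale
  corrected <- e$chip - c_$chip
  corrected[!is.na(corrected) & corrected <= 0] <- NA_real_

  ratio <- corrected / e$input
  ratio[!is.finite(ratio) | ratio <= 0] <- NA_real_
  if (all(is.na(ratio))) abort("empty track")
  med_r <- median(ratio, na.rm = TRUE)

  track <- tile_track(
    tibble(tile_id = e$tile_id, value = ratio / med_r),
    state = "ratio", assay = "seq_chip"
  )
  track <- record_step(track, "seqchip_subtract",
                       list(median_scale = med_r))
  if (!is.null(density)) track <- normalize_by_track(track, density)
  if (!is.null(igg)) track <- normalize_by_track(track, igg)
  to_zscores(track)
}

# background-correct both channels per replicate, put each replicate on a
# common input scale (median input = 1), and average replicates per tile
seqchip_channels <- function(measurements) {
  m <- as_tibble(measurements)
  req <- c("tile_id", "chip", "chip_bg", "input", "input_bg")
  miss <- setdiff(req, names(m))
  if (length(miss) > 0) {
    abort(paste0("measurement table is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (!"replicate" %in% names(m)) m$replicate <- 1L
  ok <- if ("flag" %in% names(m)) m$flag == "ok" else rep(TRUE, nrow(m))
  m$chip_c <- ifelse(ok, m$chip - m$chip_bg, NA_real_)
  m$input_c <- ifelse(ok, m$input - m$input_bg, NA_real_)
  m$input_c[!is.na(m$input_c) & m$input_c <= 0] <- NA_real_

  m %>%
    group_by(.data$replicate) %>%
    mutate(.sc = median(.data$input_c, na.rm = TRUE),
           chip_c = .data$chip_c / .data$.sc,
           input_c = .data$input_c / .data$.sc) %>%
    ungroup() %>%
    group_by(.data$tile_id) %>%
    summarise(
      chip = if (all(is.na(.data$chip_c))) NA_real_
             else mean(.data$chip_c, na.rm = TRUE),
      input = if (all(is.na(.data$input_c))) NA_real_
              else mean(.data$input_c, na.rm = TRUE),
      .groups = "drop"
    )
}
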