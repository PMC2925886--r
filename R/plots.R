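#' Plot a consensus exon-intron metaprofile
#'
#' Bar chart of mean Z per ordered feature slot with 95% confidence
#' intervals, exons and introns coloured separately, mirroring the usual
#' consensus gene-structure histogram.
#'
#' @param object A `meta_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_profile <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slot, y = .data$mean_z,
                                  fill = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_z - .data$ci,
                   ymax = .data$mean_z + .data$ci),
      width = 0.3
    ) +
    ggplot2::scale_fill_manual(
      values = c(exon = "#2166ac", intron = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "mean Z-score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot feature-class means with confidence intervals
#'
#' @param object A `class_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_summary <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$mean_z)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_z - .data$ci,
                   ymax = .data$mean_z + .data$ci),
      width = 0.3
    ) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = NULL, y = "mean Z-score") +
    ggplot2::theme_minimal()
}

#' Plot a proportional gene-length profile
#'
#' Mean Z along the flank-gene-flank percentage axis; dashed lines mark
#' the gene boundaries at 0% and 100%.
#'
#' @param object A `gene_percent_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_percent_profile <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_mid, y = .data$mean_z)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 100), linetype = "dashed") +
    ggplot2::labs(x = "position (% of gene length)", y = "mean Z-score") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap null distribution
#'
#' Histogram of randomized feature-class means with the observed mean
#' marked, one facet per class.
#'
#' @param object A `bootstrap_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  rand <- as_tibble(as.data.frame(object$randomized)) %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "class",
                        values_to = "mean")
  obs <- object$classes %>% select("class", "observed")
  ggplot2::ggplot(rand, ggplot2::aes(x = .data$mean)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "#b2182b") +
    ggplot2::facet_wrap(~class, scales = "free") +
    ggplot2::labs(x = "randomized class mean", y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
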