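#' Tidy a bootstrap result
#'
#' One row per tested feature class plus one for the exon-intron bias
#' delta Z.
#'
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @return A tibble (class, observed, rand_mean, rand_sd, p_empirical,
#'   p_parametric, n_tiles).
#' @export
tidy.bootstrap_result <- function(x, ...) {
  bind_rows(x$classes, x$delta)
}

#' @rdname tidy.bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble(
    R = x$R, sided = x$sided,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    delta_z = x$delta$observed,
    p_empirical = x$delta$p_empirical,
    p_parametric = x$delta$p_parametric
  )
}

#' Tidy adjacent-pair t-test results
#'
#' @param x A `pair_test`.
#' @param ... Unused.
#' @return One row per exon-intron pair.
#' @export
tidy.pair_test <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.pair_test
#' @export
glance.pair_test <- function(x, ...) {
  tibble(
    mode = attr(x, "mode"),
    n_pairs = sum(!is.na(x$p)),
    median_p = attr(x, "median_p")
  )
}

#' Tidy a class summary
#'
#' @param x A `class_summary`.
#' @param ... Unused.
#' @return The per-class summary tibble.
#' @export
tidy.class_summary <- function(x, ...) {
  x$summary
}

#' @rdname tidy.class_summary
#' @export
glance.class_summary <- function(x, ...) {
  x$delta
}

#' @export
generics::tidy

#' @export
generics::glance
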