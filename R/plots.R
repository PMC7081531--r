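#' Plot a fitted marker: contrast histogram with mixture components
#'
#' @param calls A `genocall` built with `keep_fits = TRUE`, or a single
#'   `mixfit`.
#' @param marker_id Marker to plot (when `calls` is a `genocall`).
#' @param signals Optional signal tibble to overlay the observed contrasts;
#'   when `calls` is a `genocall` the histogram is rebuilt from the fit's
#'   responsibilities-weighted data only if `signals` is given.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_marker_fit <- function(calls, marker_id = NULL, signals = NULL, bins = 40) {
  if (inherits(calls, "genocall")) {
    stopifnot(!is.null(calls$fits), !is.null(marker_id))
    fit <- calls$fits[[marker_id]]
  } else {
    fit <- calls
  }
  stopifnot(inherits(fit, "mixfit"))
  grid <- seq(min(fit$means) - 4 * sqrt(max(fit$variances)),
              max(fit$means) + 4 * sqrt(max(fit$variances)), length.out = 400)
  dens <- purrr::map_dfr(seq_len(fit$g), function(k) {
    tibble::tibble(cluster = factor(k), contrast = grid,
                   density = fit$weights[k] *
                     stats::dnorm(grid, fit$means[k], sqrt(fit$variances[k])))
  })
  p <- ggplot2::ggplot(dens, ggplot2::aes(.data$contrast, .data$density,
                                          colour = .data$cluster))
  if (!is.null(signals)) {
    x <- signals$contrast[signals$marker_id == marker_id]
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(contrast = x[is.finite(x)]),
      ggplot2::aes(x = .data$contrast, y = ggplot2::after_stat(!!rlang::sym("density"))),
      bins = bins, inherit.aes = FALSE, fill = "grey85", colour = NA)
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "contrast (log2 A/B)", y = "density",
                  title = if (!is.null(marker_id)) marker_id else NULL) +
    ggplot2::theme_minimal()
}

#' Plot candidate-parent exclusion-ratio distributions
#'
#' Shows per-offspring ER for the best, second-best, third-best and
#' remaining candidates -- the diagnostic used to place the assignment
#' threshold below the closest-fitting non-parent.
#'
#' @param duo_stats Tibble from [duo_stats()].
#' @param er_threshold Assignment threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_er_ranks <- function(duo_stats, er_threshold = 0.002) {
  ranked <- dplyr::mutate(
    dplyr::group_by(duo_stats, .data$offspring_id),
    rank = rank(.data$er, ties.method = "first"))
  ranked <- dplyr::ungroup(ranked)
  ranked$rank_class <- factor(ifelse(ranked$rank >= 4, "4+", ranked$rank),
                              levels = c("1", "2", "3", "4+"))
  ggplot2::ggplot(ranked, ggplot2::aes(.data$rank_class, .data$er,
                                       colour = .data$rank_class)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = er_threshold, linetype = "dashed") +
    ggplot2::labs(x = "candidate rank by ER", y = "exclusion ratio") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot a maternal recombination profile
#'
#' Heterozygous-maternal-inheritance fraction along each chromosome; the dip
#' marks the centromere, where recombination is suppressed.
#'
#' @param object A `recomb_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recomb_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position / 1e6,
                                       .data$het_fraction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = "fraction heterozygous maternal inheritance") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
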