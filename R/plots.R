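#' Plot a 2D embedding
#'
#' Scatter plot of the embedded proteins, seeds (or any chosen subset)
#' highlighted.
#'
#' @param object an [geodesic_mds()] result.
#' @param highlight optional character vector of protein ids drawn on top.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot embedding2d
#' @export
autoplot.embedding2d <- function(object, highlight = NULL, ...) {
  co <- object$coords
  p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5, colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2",
                  title = sprintf("Geodesic MDS (%s), stress %.3f",
                                  object$method, object$stress)) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_point(data = co[co$id %in% highlight, , drop = FALSE],
                                 colour = "firebrick", size = 1.2)
  }
  p
}

#' Plot a density grid
#'
#' Raster image of the per-cell protein density, the numeric counterpart of
#' the density-coloured map images.
#'
#' @param object a [density_grid()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot density_grid
#' @export
autoplot.density_grid <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$x, y = .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2",
                  fill = if (object$mode == "count") "proteins/cell" else "density") +
    ggplot2::theme_minimal()
}

#' Plot an empirical null with an observed distance
#'
#' Histogram of the all-pairs distance values, the fitted normal curve, and
#' (optionally) a vertical line at an observed distance.
#'
#' @param object a [null_distribution()].
#' @param observed optional observed distance (jumps) to mark.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  v <- tidy(object)
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::stat_function(fun = stats::dnorm,
                           args = list(mean = object$mean, sd = max(object$sd, 1e-12)),
                           colour = "steelblue") +
    ggplot2::labs(x = sprintf("%s (jumps)", object$statistic), y = "density",
                  title = sprintf("%d comparisons: mean %.2f, sd %.2f",
                                  object$n_comparisons, object$mean, object$sd)) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "firebrick",
                                 linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
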