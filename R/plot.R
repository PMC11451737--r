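#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 2D spectrum as a contour-style heat map
#'
#' Axes follow the NMR display convention (ppm decreasing left to right and
#' bottom to top).
#'
#' @param object A [spectrum2d()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum2d
#' @export
autoplot.spectrum2d <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$direct_ppm, .data$indirect_ppm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = paste0(object$nucleus_direct, " (ppm)"),
                  y = paste0(object$nucleus_indirect, " (ppm)"),
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a 1D slice
#'
#' @param object A [slice1d()].
#' @param ... Unused.
#' @return A ggplot object (ppm decreasing left to right).
#' @method autoplot slice1d
#' @export
autoplot.slice1d <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$ppm, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = paste0(object$nucleus, " (ppm)"), y = "intensity",
                  subtitle = paste0("fixed ", object$fixed_dimension, " = ",
                                    format(object$fixed_ppm), " ppm")) +
    ggplot2::theme_minimal()
}

#' Plot a 2D histogram (Ramachandran or crosspeak surface)
#'
#' @param object A `histogram2d`.
#' @param ... Unused.
#' @return A ggplot object; shift axes are reversed per NMR convention,
#'   torsion axes are not.
#' @method autoplot histogram2d
#' @export
autoplot.histogram2d <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = object$labels[1], y = object$labels[2]) +
    ggplot2::theme_minimal()
  if (identical(object$axis_kind, "shift")) {
    p <- p + ggplot2::scale_x_reverse() + ggplot2::scale_y_reverse()
  }
  p
}

#' Plot original, reweighted and difference crosspeaks side by side
#'
#' @param object A `reweight_result` from [reweight_crosspeak()].
#' @param ... Unused.
#' @return A ggplot object with three facets.
#' @method autoplot reweight_result
#' @export
autoplot.reweight_result <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("original", "reweighted", "difference"),
                              names_to = "panel", values_to = "weight")
  long$panel <- factor(long$panel, c("original", "reweighted", "difference"))
  ggplot2::ggplot(long, ggplot2::aes(.data$x_ppm, .data$y_ppm,
                                     fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = paste0(object$original$labels[1], " (ppm)"),
                  y = paste0(object$original$labels[2], " (ppm)")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of relative center-of-mass coordinates
#'
#' Displays each crosspeak's centers of mass relative to the per-crosspeak
#' mean, with error bars from the noise-injection uncertainties: the usual
#' way of judging whether two conditions displace any crosspeak beyond its
#' uncertainties.
#'
#' @param com Result of [compare_com()].
#' @return A ggplot object.
#' @export
plot_com_comparison <- function(com) {
  df <- com$table[!com$table$failed, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$rel_x, .data$rel_y,
                                   colour = .data$condition,
                                   shape = .data$side)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rel_y - .data$sigma_y,
                                        ymax = .data$rel_y + .data$sigma_y),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$rel_x - .data$sigma_x,
                                         xmax = .data$rel_x + .data$sigma_x),
                            height = 0) +
    ggplot2::facet_wrap(~crosspeak) +
    ggplot2::labs(x = "relative direct ppm", y = "relative indirect ppm") +
    ggplot2::theme_minimal()
}
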