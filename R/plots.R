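#' Plot a tessellation
#'
#' Cell outlines (and optionally seeds) with ggplot2; 3D tessellations are
#' drawn in their first two coordinates.
#'
#' @param tess a `tessellation`.
#' @param show_seeds draw cell seed points.
#' @return A ggplot object.
#' @export
plot_tessellation <- function(tess, show_seeds = TRUE) {
  segs <- do.call(rbind, lapply(seq_along(tess$faces), function(i) {
    f <- tess$faces[[i]]
    j <- c(f[-1], f[1])
    data.frame(x = tess$vertices[f, 1], y = tess$vertices[f, 2],
               xend = tess$vertices[j, 1], yend = tess$vertices[j, 2])
  }))
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  if (show_seeds) {
    ctr <- data.frame(x = tess$centers[, 1], y = tess$centers[, 2])
    p <- p + ggplot2::geom_point(data = ctr,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 size = 0.4, colour = "firebrick")
  }
  p
}

#' @export
autoplot.growth_trajectory <- function(object, ...) {
  s <- object$summary |>
    tidyr::pivot_longer(c("coverage", "voronoi_deviation", "gap_max"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$cycle, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "growth cycle", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dist_summary <- function(object, ...) {
  df <- data.frame(x = object$mids, density = object$density_max1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "value / peak", y = "density (max = 1)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.peak_regression <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("log_peak", "log_area")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_area, y = .data$log_peak)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::geom_abline(slope = object$isometric_exponent,
                         intercept = mean(d$log_peak) -
                           object$isometric_exponent * mean(d$log_area),
                         linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "log10 surface area", y = "log10 peak value",
                  subtitle = sprintf("m' = %.3f (isometric m = %.2f)",
                                     object$slope,
                                     object$isometric_exponent)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
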