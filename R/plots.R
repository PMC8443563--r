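#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_vline labs scale_fill_viridis_c coord_equal theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a dehydration contrast series with its logistic fit
#'
#' @param object A [fit_logistic()] result.
#' @param ... Unused.
#' @return A ggplot: normalized contrast, fitted logistic, and the
#'   plasmolysis time (derivative peak) as a vertical line.
#' @export
autoplot.logistic_fit <- function(object, ...) {
  s <- object$series
  ggplot(s, aes(x = .data$time)) +
    geom_point(aes(y = .data$contrast_norm), size = 0.8, alpha = 0.6) +
    geom_line(aes(y = .data$fitted), colour = "red") +
    geom_vline(xintercept = object$params$t0, linetype = "dashed") +
    labs(x = "time (h)", y = "normalized global contrast",
         title = sprintf("logistic fit: t0 = %.2f h, k = %.2f /h",
                         object$params$t0, object$params$k)) +
    theme_minimal()
}

#' Plot a minor-axis-length curve with its extrema
#'
#' @param object A [build_minor_axis_curve()] result.
#' @param ... Unused.
#' @return A ggplot of l_k per frame; extrema coloured by kind.
#' @export
autoplot.minor_axis_curve <- function(object, ...) {
  ext <- attr(object, "extrema")
  p <- ggplot(as_tibble(object), aes(x = .data$frame, y = .data$minor_len)) +
    geom_line(colour = "grey50") + geom_point(size = 1) +
    labs(x = "frame k", y = "minor axis length l_k (um)") +
    theme_minimal()
  if (nrow(ext) > 0)
    p <- p + geom_point(data = ext,
                        aes(x = .data$frame, y = .data$value,
                            colour = .data$kind), size = 2.5)
  p
}

#' Plot recovered rolling angles
#'
#' @param object An `angle_series` from [unwrap_angles()].
#' @param ... Unused.
#' @return A ggplot of theta_k per frame; invalid (local-extreme) frames
#'   shown as crosses.
#' @export
autoplot.angle_series <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$frame, y = .data$theta_deg)) +
    geom_line(colour = "grey70") +
    geom_point(aes(shape = .data$valid, colour = .data$valid), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    labs(x = "frame k", y = "rolling angle theta_k (deg)") +
    theme_minimal()
}

#' Plot the protoplast/cell area-ratio trend
#'
#' @param object An `area_trend` from [area_ratio_trend()].
#' @param ... Unused.
#' @return A ggplot with the post-plasmolysis linear fit.
#' @export
autoplot.area_trend <- function(object, ...) {
  sl <- attr(object, "slope"); ic <- attr(object, "intercept")
  d <- as_tibble(object)
  ggplot(d, aes(x = .data$time, y = .data$ratio_percent)) +
    geom_point(aes(colour = .data$post_plasmolysis)) +
    ggplot2::geom_abline(slope = sl, intercept = ic, colour = "red") +
    geom_vline(xintercept = attr(object, "t_plasmolysis"),
               linetype = "dashed") +
    labs(x = "time (h)", y = "A_P / A_C (%)",
         title = sprintf("post-plasmolysis slope %.2f %%/h", sl)) +
    theme_minimal()
}

#' Plot an orthogonal tomogram slice
#'
#' @param tomo A [tomogram()].
#' @param axis,index Passed to [slice_tomogram()].
#' @return A ggplot raster of refractive index with physical coordinates.
#' @export
plot_slice <- function(tomo, axis = "x", index = NULL) {
  sl <- slice_tomogram(tomo, axis = axis, index = index)
  co <- attr(sl, "coords")
  d <- tidyr::expand_grid(row = co$row, col = co$col)
  d$ri <- as.vector(sl)
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$ri)) +
    geom_raster() + scale_fill_viridis_c(name = "RI") +
    coord_equal() +
    labs(x = "um", y = "um",
         title = sprintf("central slice (axis %s)", attr(sl, "axis"))) +
    theme_minimal()
}
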