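#' Plot an instance label map
#'
#' Raster plot of a label map with one color per instance (background dark),
#' in image orientation (row 1 at the top).
#'
#' @param map integer label matrix.
#' @return a ggplot object.
#' @export
plot_label_map <- function(map) {
  df <- expand.grid(y = seq_len(nrow(map)), x = seq_len(ncol(map)))
  df$label <- factor(as.vector(map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "instance") +
    ggplot2::theme_void()
}

#' Automated-vs-manual agreement scatterplot
#'
#' The usual agreement panel: automated values on x, manual on y, with the
#' fitted regression line and the identity line.
#'
#' @param object a `trait_agreement` fit.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trait_agreement <- function(object, ...) {
  df <- data.frame(auto = object$auto, manual = object$manual)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auto, y = .data$manual)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", color = "grey50") +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, color = "steelblue"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "automated", y = "manual",
      subtitle = sprintf(
        "R² = %.3f%s", object$r_squared,
        if (is.na(object$mape_percent)) "" else sprintf(", MAPE = %.2f%%", object$mape_percent)
      )
    ) +
    ggplot2::theme_minimal()
}
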