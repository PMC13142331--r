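# ggplot2 presentation of the result types.

#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  kind <- attr(object, "kind")
  ylab <- switch(kind,
                 autocorr = "g(r)",
                 crosscorr = "cross-correlation g(r)",
                 L_minus_LCSR = expression(L(r) - L(r)[CSR] ~ "(nm)"),
                 crossL_minus_LCSR = expression(L[AB](r) - L(r)[CSR] ~ "(nm)"),
                 nn_cdf = "cumulative probability",
                 "value")
  ref <- switch(kind, autocorr = 1, crosscorr = 1,
                L_minus_LCSR = 0, crossL_minus_LCSR = 0, NULL)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$value))
  if (any(is.finite(object$dispersion))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$dispersion,
                   ymax = .data$value + .data$dispersion),
      fill = "steelblue", alpha = 0.25)
  }
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_hline(yintercept = ref, linetype = "dashed",
                                 colour = "grey50")
  }
  p + ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "r (nm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @method autoplot density_image
#' @export
autoplot.density_image <- function(object, trans = "sqrt", ...) {
  ctr <- pixel_centres(object)
  df <- expand.grid(x = ctr$x, y = ctr$y)
  df$count <- as.vector(object$counts)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' @method autoplot condensate_mask
#' @export
autoplot.condensate_mask <- function(object, ...) {
  px <- object$pixel_size_nm
  df <- expand.grid(x = object$origin[1] + (seq_len(nrow(object$labels)) - 0.5) * px,
                    y = object$origin[2] + (seq_len(ncol(object$labels)) - 0.5) * px)
  df$region <- factor(as.vector(object$labels))
  ggplot2::ggplot(df[df$region != "0", ],
                  ggplot2::aes(.data$x, .data$y, fill = .data$region)) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::coord_equal(xlim = c(0, nrow(object$labels) * px),
                         ylim = c(0, ncol(object$labels) * px)) +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Overlay detected sites on an event map
#'
#' @param events Event tibble (`x`, `y`).
#' @param sites Site tibble from [detect_sites()].
#' @return A ggplot object.
#' @export
plot_sites <- function(events, sites) {
  ggplot2::ggplot(events, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.3, colour = "grey40") +
    ggplot2::geom_point(data = sites, colour = "red", shape = 1, size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
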