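#' Plot a decoded timing signal
#'
#' @param object An `ae_decoded`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ae_decoded <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = "decoded amplitude",
                  title = paste(attr(object, "method"), "decoded timing signal"),
                  subtitle = if (!is.na(attr(object, "frequency") %||% NA)) {
                    sprintf("dominant harmonic: %.3g Hz", attr(object, "frequency"))
                  }) +
    ggplot2::theme_minimal()
}

#' Plot a harmonic amplitude spectrum
#'
#' @param object A `harmonic_fit`.
#' @param max_freq Upper frequency limit for display, Hz.
#' @param ... Unused.
#' @return A ggplot of harmonic amplitude vs frequency.
#' @export
autoplot.harmonic_fit <- function(object, max_freq = 50, ...) {
  df <- dplyr::filter(tidy(object), .data$frequency <= max_freq)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$amplitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$frequency, yend = 0)) +
    ggplot2::labs(x = "frequency (Hz)", y = "harmonic amplitude") +
    ggplot2::theme_minimal()
}

#' Plot an amplitude or dB image map
#'
#' @param object An `ae_image` or `ae_image_db`.
#' @param ... Unused.
#' @return A ggplot raster in hot colors (dB maps span the configured
#'   dynamic range).
#' @export
autoplot.ae_image <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colors = c("black", "red", "yellow", "white")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "amplitude") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ae_image
#' @export
autoplot.ae_image_db <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colors = c("black", "red", "yellow", "white"),
      limits = c(-attr(object, "dynamic_range"), 0)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "dB") +
    ggplot2::theme_minimal()
}

#' Plot a line profile
#'
#' @param object An `ae_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ae_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%s (mm)", attr(object, "axis")),
                  y = "amplitude",
                  subtitle = sprintf("at %s = %g mm",
                                     setdiff(c("x", "y"), attr(object, "axis")),
                                     attr(object, "fixed"))) +
    ggplot2::theme_minimal()
}
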