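#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Raster plot of a frame image or dose map
#' @param object A `frame_image` / `dose_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frame_image <- function(object, ...) {
  df <- tidy.frame_image(object)
  lab <- switch(attr(object, "units"),
                cGy = "dose (cGy)", ADU = "signal (ADU)", "relative")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y_mm, y = .data$x_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "crossplane (mm)", y = "inplane (mm)") +
    ggplot2::theme_minimal()
}

#' Radial-profile plot of a kernel (log scale)
#' @param object A [kernel()].
#' @param n_bins Annuli (default 48).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kernel <- function(object, n_bins = 48, ...) {
  df <- radial_profile(object, n_bins)
  df <- df[!is.na(df$value) & df$value > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_mm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from central axis (mm)",
                  y = "kernel value (per pixel)",
                  title = paste(attr(object, "kind"), "kernel")) +
    ggplot2::theme_minimal()
}

#' Map of gamma values with failing pixels highlighted
#' @param object A `gamma_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gamma_result <- function(object, ...) {
  df <- tidy.gamma_result(object)
  df <- df[df$evaluated, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = pmin(.data$gamma, 2))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "red", midpoint = 1,
                                  name = "gamma") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("gamma %s: %.1f%% pass",
                      format_criteria(object$criteria),
                      object$pass_rate_pct),
      x = "column (px)", y = "row (px)"
    ) +
    ggplot2::theme_minimal()
}

#' Overlayed dose profiles
#'
#' @param doses Named list of `frame_image`/`dose_map` objects.
#' @param axis,offset_mm As in [extract_profile()].
#' @return A ggplot of the profiles.
#' @export
plot_profiles <- function(doses, axis = "crossplane", offset_mm = 0) {
  df <- dplyr::bind_rows(purrr::imap(doses, function(d, nm) {
    dplyr::mutate(extract_profile(d, axis, offset_mm), source = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position_mm, y = .data$value,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (mm)", y = "value") +
    ggplot2::theme_minimal()
}
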