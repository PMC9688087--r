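#' Plot a probe temperature series
#'
#' @param object A `probe`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.probe <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$delta_t_c)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * T ~ (degree * C)),
                  title = sprintf("probe %s at (%s) mm", attr(object, "mode"),
                                  paste(attr(object, "position_mm"),
                                        collapse = ", ")))
}

#' Plot a temperature-field plane map
#'
#' @param field A `temperature_field`.
#' @param axis,offset_mm Plane selection, see [plane_map()].
#' @return A ggplot raster of the temperature rise.
#' @export
plot_plane <- function(field, axis = "z", offset_mm = 0) {
  df <- plane_map(field, axis, offset_mm)
  nm <- names(df)[1:2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                                   fill = .data$delta_t_c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * T ~ (degree * C))) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s = %g mm plane at t = %g s",
                                  axis, offset_mm, field$time))
}

#' Plot a nanorod absorption spectrum
#'
#' @param object A tibble from [cross_section_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm,
                                       y = .data$c_abs_nm2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(C[abs] ~ (nm^2)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
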