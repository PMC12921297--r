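#' Plot a dose map
#'
#' @param object A [dose_map()].
#' @param ... Unused.
#' @return A ggplot raster of the dose distribution.
#' @export
autoplot.dose_map <- function(object, ...) {
  df <- tidyr::expand_grid(z_mm = .map_z(object), x_mm = .map_x(object))
  df$dose_Gy <- as.vector(object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$z_mm, fill = .data$dose_Gy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Dose [Gy]") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$plane, x = "x [mm]", y = "z [mm]") +
    ggplot2::theme_minimal()
}

#' Plot an oxygen trace
#'
#' @param object An [o2_trace()].
#' @param ... Unused.
#' @return A ggplot of concentration vs time with the shot marked.
#' @export
autoplot.o2_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$o2_uM)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "shot_time_s"),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "Time [s]", y = expression(O[2] ~ "[µM]"),
                  title = sprintf("Oxygen trace (%s)", attr(object, "medium"))) +
    ggplot2::theme_minimal()
}

#' Plot an oxygen-yield fit
#'
#' @param object A [fit_o2_slope()] result.
#' @param ... Unused.
#' @return A ggplot of drop vs dose with the origin-constrained fit line.
#' @export
autoplot.yield_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dose_Gy, .data$drop_uM)) +
    ggplot2::geom_abline(slope = object$slope_uM_Gy, intercept = 0,
                         linetype = "dashed", color = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::expand_limits(x = 0, y = 0) +
    ggplot2::labs(x = "Dose [Gy]", y = expression(Delta * O[2] ~ "[µM]"),
                  title = sprintf("%s: %.2f µM/Gy", object$medium,
                                  object$slope_uM_Gy)) +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed spectrum fit
#'
#' @param object A [fit_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot comparing measured and modeled region doses.
#' @export
autoplot.spectrum_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$residuals,
                            c("dose_Gy", "modeled_Gy"),
                            names_to = "which", values_to = "dose")
  df$which <- ifelse(df$which == "dose_Gy", "measured", "modeled")
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$dose, fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~plane, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Dose [Gy]", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an electron spectrum model
#'
#' @param object An [electron_spectrum()].
#' @param e_max_MeV Upper energy (MeV).
#' @param ... Unused.
#' @return A ggplot of the on-axis differential fluence (log scale).
#' @export
autoplot.electron_spectrum <- function(object, e_max_MeV = 100, ...) {
  df <- tibble::tibble(energy_MeV = seq(0.1, e_max_MeV, length.out = 400))
  df$fluence <- eval_spectrum(object, df$energy_MeV, object$alpha0)
  ggplot2::ggplot(df, ggplot2::aes(.data$energy_MeV, .data$fluence)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Kinetic energy [MeV]",
                  y = expression("dN/dE/d" * Omega ~ "[MeV"^-1 * "sr"^-1 * "]")) +
    ggplot2::theme_minimal()
}
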