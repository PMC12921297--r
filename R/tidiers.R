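#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a spectrum reconstruction
#'
#' @param x A [fit_spectrum()] result.
#' @param ... Unused.
#' @return One row per fitted parameter: `term`, `estimate`, `unit`.
#' @export
tidy.spectrum_fit <- function(x, ...) {
  m <- x$fitted_model
  tibble::tibble(
    term = c("n0", "lambda", "t1", "t2", "alpha0", "delta_alpha"),
    estimate = c(m$n0, m$lambda, m$t1, m$t2, m$alpha0, m$delta_alpha),
    unit = c("MeV^-1 sr^-1", "", "MeV", "MeV", "deg", "deg"))
}

#' @rdname tidy.spectrum_fit
#' @export
glance.spectrum_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective_value, converged = x$converged,
                 n_iterations = x$n_iterations, n_regions = nrow(x$residuals),
                 tank_dose_Gy = x$tank_dose_Gy, seed = x$seed)
}

#' Tidy an oxygen-yield fit
#'
#' @param x A [fit_o2_slope()] result.
#' @param ... Unused.
#' @return Broom-style coefficient table (single origin-constrained slope).
#' @export
tidy.yield_fit <- function(x, ...) {
  tibble::tibble(term = "slope_uM_Gy", estimate = x$slope_uM_Gy,
                 std.error = x$stderr_uM_Gy)
}

#' @rdname tidy.yield_fit
#' @export
glance.yield_fit <- function(x, ...) {
  tibble::tibble(slope_uM_Gy = x$slope_uM_Gy, stderr_uM_Gy = x$stderr_uM_Gy,
                 n_shots = x$n_shots, medium = x$medium)
}
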