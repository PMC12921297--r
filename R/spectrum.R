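#' Two-temperature electron spectrum model
#'
#' Parametric model of a direct-laser-acceleration electron beam: the
#' differential fluence per unit energy and solid angle is a weighted sum
#' of two exponentials in kinetic energy, multiplied by a Gaussian angular
#' profile,
#' \deqn{f(E, \alpha) = N_0\,[\lambda e^{-E/T_1} + (1-\lambda) e^{-E/T_2}]\,
#'       e^{-((\alpha-\alpha_0)/\Delta\alpha)^2}.}
#' The two effective temperatures are stored in canonical order
#' `t1 <= t2`; if supplied the other way round they are swapped and
#' `lambda` is replaced by `1 - lambda`, which leaves the model pointwise
#' identical.
#'
#' @param n0 Normalization (MeV^-1 sr^-1), > 0.
#' @param lambda Fraction of the `t1` population, in \[0, 1\].
#' @param t1,t2 Effective temperatures (MeV), > 0.
#' @param alpha0 Beam pointing angle w.r.t. the laser axis (degrees).
#' @param delta_alpha Gaussian divergence parameter (degrees), > 0. The
#'   half-angle at half maximum is `delta_alpha * sqrt(log(2))`.
#'
#' @return An object of class `electron_spectrum`.
#' @export
#' @examples
#' m <- electron_spectrum(1e12, 0.35, 7, 14, 0, 13)
#' eval_spectrum(m, energy = 10, angle = 0)
electron_spectrum <- function(n0, lambda, t1, t2, alpha0 = 0, delta_alpha = 10) {
  stopifnot(is.numeric(n0), length(n0) == 1L, is.finite(n0))
  if (n0 <= 0) stop("`n0` must be positive", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("`lambda` must lie in [0, 1]", call. = FALSE)
  if (t1 <= 0 || t2 <= 0) stop("temperatures must be positive", call. = FALSE)
  if (delta_alpha <= 0) stop("`delta_alpha` must be positive", call. = FALSE)
  if (t1 > t2) {
    tmp <- t1; t1 <- t2; t2 <- tmp
    lambda <- 1 - lambda
  }
  structure(
    list(n0 = n0, lambda = lambda, t1 = t1, t2 = t2,
         alpha0 = alpha0, delta_alpha = delta_alpha),
    class = "electron_spectrum"
  )
}

#' @export
print.electron_spectrum <- function(x, ...) {
  cat("<electron_spectrum>\n")
  cat(sprintf("  N0 = %.4g MeV^-1 sr^-1\n", x$n0))
  cat(sprintf("  lambda = %.3f, T1 = %.3g MeV, T2 = %.3g MeV\n",
              x$lambda, x$t1, x$t2))
  cat(sprintf("  alpha0 = %.2f deg, delta_alpha = %.2f deg (HWHM %.2f deg)\n",
              x$alpha0, x$delta_alpha, fwhm_half_angle(x$delta_alpha)))
  invisible(x)
}

#' Evaluate the differential electron fluence
#'
#' @param model An [electron_spectrum()].
#' @param energy Kinetic energy (MeV), >= 0; vectorized.
#' @param angle Polar angle w.r.t. the laser axis (degrees); vectorized.
#' @return Differential fluence (MeV^-1 sr^-1), strictly positive and
#'   non-increasing in energy at fixed angle.
#' @export
eval_spectrum <- function(model, energy, angle = model$alpha0) {
  stopifnot(inherits(model, "electron_spectrum"))
  if (any(energy < 0)) stop("`energy` must be non-negative", call. = FALSE)
  spec <- model$lambda * exp(-energy / model$t1) +
    (1 - model$lambda) * exp(-energy / model$t2)
  ang <- exp(-((angle - model$alpha0) / model$delta_alpha)^2)
  model$n0 * spec * ang
}

#' Half-angle at half maximum of the angular profile
#'
#' For the Gaussian angular factor `exp(-((a - a0)/da)^2)` the half width
#' at half maximum is `da * sqrt(log(2))`.
#'
#' @param delta_alpha Divergence parameter (degrees), > 0.
#' @return Half-angle (degrees).
#' @export
fwhm_half_angle <- function(delta_alpha) {
  if (any(delta_alpha <= 0)) stop("`delta_alpha` must be positive", call. = FALSE)
  delta_alpha * sqrt(log(2))
}

#' Beam charge in an energy band over a solid angle
#'
#' Integrates the on-axis (`alpha = alpha0`) spectrum analytically over
#' `[e_min, e_max]` and multiplies by the supplied solid angle, treating
#' the angular distribution as flat over that solid angle — the convention
#' used when quoting "charge within Omega above E" for a directed beam. An
#' angular convolution is performed by the forward dose model instead.
#'
#' @param model An [electron_spectrum()].
#' @param e_min,e_max Energy band (MeV), `e_min < e_max`; `e_max = Inf` allowed.
#' @param solid_angle Solid angle (sr), > 0.
#' @return Charge in nC.
#' @export
#' @examples
#' m <- electron_spectrum(1.3e11, 0, 13, 14.5, 0, 13)
#' beam_charge(m, 7.5, Inf, 0.16)
beam_charge <- function(model, e_min, e_max = Inf, solid_angle) {
  stopifnot(inherits(model, "electron_spectrum"))
  if (e_min >= e_max) stop("`e_min` must be less than `e_max`", call. = FALSE)
  if (solid_angle <= 0) stop("`solid_angle` must be positive", call. = FALSE)
  part <- function(t) t * (exp(-e_min / t) - exp(-e_max / t))
  n <- model$n0 * (model$lambda * part(model$t1) +
                     (1 - model$lambda) * part(model$t2))
  n * solid_angle * .const$e_charge_C * 1e9
}

#' Effective temperature from a measured spectrum
#'
#' Unweighted least-squares fit of `log(fluence)` against energy;
#' the effective temperature is minus the reciprocal slope. On data from a
#' single exponential `exp(-E/T)` this recovers `T` exactly.
#'
#' @param points A data frame with columns `energy_MeV` and `fluence`
#'   (fluences strictly positive), at least 3 rows.
#' @return Effective temperature (MeV).
#' @export
fit_temperature <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("energy_MeV", "fluence") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(points$fluence <= 0)) stop("fluences must be positive", call. = FALSE)
  fit <- stats::lm(log(fluence) ~ energy_MeV, data = points)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop("non-decreasing spectrum: effective temperature is not finite",
         call. = FALSE)
  }
  -1 / slope
}

#' Critical plasma electron density
#'
#' The density at which the plasma frequency equals the laser frequency,
#' `n_cr = eps0 m_e omega^2 / e^2` with `omega = 2 pi c / lambda`;
#' approximately `1.115e21 / lambda_um^2` cm^-3.
#'
#' @param wavelength_um Laser wavelength (micrometres), > 0.
#' @return Critical density (cm^-3).
#' @export
#' @examples
#' critical_density(1.053) # ~1.0e21
critical_density <- function(wavelength_um) {
  if (any(wavelength_um <= 0)) stop("`wavelength_um` must be positive", call. = FALSE)
  omega <- 2 * pi * .const$c_m_s / (wavelength_um * 1e-6)
  n_m3 <- .const$eps0_F_m * .const$m_e_kg * omega^2 / .const$e_charge_C^2
  n_m3 * 1e-6
}

#' Fully ionized foam electron density
#'
#' Electron density of a fully ionized low-density foam,
#' `n_e = rho N_A (Z/A)`. The foam stoichiometry (hence Z/A) is a
#' parameter: typical CHO aerogels have Z/A close to 0.53.
#'
#' @param mass_density_mg_cm3 Foam mass density (mg/cm^3), > 0.
#' @param z_over_a Mean ratio of atomic number to mass number, > 0.
#' @param wavelength_um Optional laser wavelength; when supplied the result
#'   carries an attribute `ratio_to_critical`.
#' @return Electron density (cm^-3).
#' @export
foam_electron_density <- function(mass_density_mg_cm3, z_over_a,
                                  wavelength_um = NULL) {
  if (any(mass_density_mg_cm3 <= 0) || any(z_over_a <= 0)) {
    stop("density and Z/A must be positive", call. = FALSE)
  }
  n_e <- mass_density_mg_cm3 * 1e-3 * .const$N_A * z_over_a
  if (!is.null(wavelength_um)) {
    attr(n_e, "ratio_to_critical") <- n_e / critical_density(wavelength_um)
  }
  n_e
}

#' Laser pulse description
#'
#' @param energy_fwhm_J Pulse energy within the FWHM spot (J).
#' @param duration_s Pulse duration (s), within \[1e-15, 1e-8\].
#' @param spot_major_um,spot_minor_um FWHM diameters of the (elliptical)
#'   focal spot (micrometres).
#' @param wavelength_um Central wavelength (micrometres).
#' @return An object of class `laser_pulse`.
#' @export
laser_pulse <- function(energy_fwhm_J, duration_s, spot_major_um,
                        spot_minor_um, wavelength_um = 1.053) {
  vals <- c(energy_fwhm_J, duration_s, spot_major_um, spot_minor_um, wavelength_um)
  if (any(vals <= 0)) stop("all laser pulse parameters must be positive", call. = FALSE)
  if (duration_s < 1e-15 || duration_s > 1e-8) {
    stop("`duration_s` outside the [1e-15, 1e-8] s sanity window", call. = FALSE)
  }
  structure(
    list(energy_fwhm_J = energy_fwhm_J, duration_s = duration_s,
         spot_major_um = spot_major_um, spot_minor_um = spot_minor_um,
         wavelength_um = wavelength_um),
    class = "laser_pulse"
  )
}

#' Order-of-magnitude peak intensity estimate
#'
#' `I = E_FWHM / (tau_FWHM * A_FWHM)` with the elliptical spot area
#' `A = pi (a/2)(b/2)` for FWHM diameters a, b. This is an
#' order-of-magnitude estimator, not a full spatiotemporal deconvolution.
#'
#' @param pulse A [laser_pulse()].
#' @return Peak intensity (W/cm^2).
#' @export
#' @examples
#' peak_intensity(laser_pulse(17, 750e-15, 12, 15)) # ~1.6e19
peak_intensity <- function(pulse) {
  stopifnot(inherits(pulse, "laser_pulse"))
  area_cm2 <- pi * (pulse$spot_major_um * 1e-4 / 2) *
    (pulse$spot_minor_um * 1e-4 / 2)
  pulse$energy_fwhm_J / (pulse$duration_s * area_cm2)
}

#' Mean dose rate
#'
#' @param dose_Gy Dose (Gy), >= 0.
#' @param duration_s Delivery duration (s), > 0.
#' @return Mean dose rate (Gy/s).
#' @export
#' @examples
#' mean_dose_rate(70, 1e-12) # 7e13
mean_dose_rate <- function(dose_Gy, duration_s) {
  if (any(duration_s <= 0)) stop("`duration_s` must be positive", call. = FALSE)
  dose_Gy / duration_s
}
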