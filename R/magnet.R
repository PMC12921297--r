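#' Hard-edge dipole magnet
#'
#' @param field_T Field strength (T), >= 0.
#' @param length_mm Effective length of the field region (mm), > 0.
#' @param position_mm Axial position of the magnet entrance, mm from target.
#' @return An object of class `magnet_block`.
#' @export
magnet_block <- function(field_T, length_mm = 50, position_mm = 30) {
  if (field_T < 0) stop("`field_T` must be >= 0", call. = FALSE)
  if (length_mm <= 0) stop("`length_mm` must be positive", call. = FALSE)
  structure(list(field_T = field_T, length_mm = length_mm,
                 position_mm = position_mm),
            class = "magnet_block")
}

# relativistic momentum in MeV/c
.momentum_MeV_c <- function(energy_MeV) {
  sqrt(energy_MeV^2 + 2 * energy_MeV * .const$m_e_c2_MeV)
}

#' Lateral displacement in a hard-edge dipole
#'
#' Hard-edge model: gyroradius `r[m] = p[MeV/c] / (299.792458 B[T])`, bend
#' angle `theta = asin(L/r)`, lateral displacement at a downstream plane
#' equal to the sagitta inside the magnet plus `drift * tan(theta)`.
#' Displacement decreases monotonically with energy and is zero at zero
#' field. Electrons with gyroradius smaller than the magnet length are
#' swept out of the beamline; these are flagged with the sentinel `Inf`
#' rather than an error.
#'
#' @param magnet A [magnet_block()].
#' @param energy_MeV Kinetic energy at the magnet (MeV), > 0; vectorized.
#' @param drift_mm Field-free drift from magnet exit to the plane (mm).
#' @return Lateral displacement (mm); `Inf` marks swept-out electrons.
#' @export
magnet_deflection <- function(magnet, energy_MeV, drift_mm) {
  stopifnot(inherits(magnet, "magnet_block"))
  if (any(energy_MeV <= 0)) stop("`energy_MeV` must be positive", call. = FALSE)
  if (magnet$field_T == 0) return(rep(0, length(energy_MeV)))
  r_mm <- .momentum_MeV_c(energy_MeV) / (299.792458 * magnet$field_T) * 1000
  out <- rep(Inf, length(energy_MeV))
  ok <- r_mm > magnet$length_mm
  theta <- asin(magnet$length_mm / r_mm[ok])
  sagitta <- r_mm[ok] * (1 - cos(theta))
  out[ok] <- sagitta + drift_mm * tan(theta)
  out
}

#' Energy from deflection in a magnetic spectrometer
#'
#' Inverts the hard-edge dipole deflection map at fixed field: given the
#' lateral position of a trace on the detector plate, returns the electron
#' kinetic energy. Energy decreases strictly with increasing deflection.
#'
#' @param position_mm Lateral displacement on the plate (mm), > 0;
#'   vectorized.
#' @param magnet A [magnet_block()]; default is the 0.99 T spectrometer
#'   with a compact 4 mm effective field length (a hard-edge dipole only
#'   transmits electrons whose gyroradius exceeds the field length, so a
#'   spectrometer meant to resolve electrons down to ~1 MeV must be short).
#' @param drift_mm Drift from magnet exit to the plate (mm).
#' @param e_range_MeV Search bracket for the inversion (MeV).
#' @return Kinetic energy (MeV).
#' @export
spectrometer_dispersion <- function(position_mm,
                                    magnet = magnet_block(0.99, 4, 0),
                                    drift_mm = 100,
                                    e_range_MeV = c(0.1, 1000)) {
  stopifnot(inherits(magnet, "magnet_block"))
  # lowest energy still transmitted (gyroradius > magnet length)
  p_min <- magnet$length_mm / 1000 * 299.792458 * magnet$field_T * 1.001
  e_min_inv <- sqrt(p_min^2 + .const$m_e_c2_MeV^2) - .const$m_e_c2_MeV
  e_lo <- max(e_range_MeV[1], e_min_inv)
  lo <- magnet_deflection(magnet, e_range_MeV[2], drift_mm)
  hi <- magnet_deflection(magnet, e_lo, drift_mm)
  vapply(position_mm, function(x) {
    if (!is.finite(x) || x < lo || x > hi) {
      stop(sprintf("position %g mm outside the invertible branch [%g, %g] mm",
                   x, lo, hi), call. = FALSE)
    }
    stats::uniroot(function(e) magnet_deflection(magnet, e, drift_mm) - x,
                   interval = c(e_lo, e_range_MeV[2]), tol = 1e-10)$root
  }, numeric(1))
}
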