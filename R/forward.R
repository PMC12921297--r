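#' Quadrature and sampling controls for the forward dose model
#'
#' @param n_energy Number of log-spaced energy nodes (trapezoid rule).
#' @param e_min_MeV,e_max_MeV Energy integration band (MeV); `e_max_MeV`
#'   is clipped to the stopping-power table maximum.
#' @param sample_spacing_mm Transverse sampling lattice spacing used to
#'   average the modeled dose over a region (the lattice is anchored at
#'   multiples of the spacing, so with matching pixel size it coincides
#'   with dose-map pixel centers).
#' @param tank_axial_n Number of axial slices for the tank volume average.
#' @param tank_spacing_mm Transverse sampling spacing inside the tank.
#' @return A list of class `forward_control`.
#' @export
forward_control <- function(n_energy = 160, e_min_MeV = 0.15, e_max_MeV = 150,
                            sample_spacing_mm = 1, tank_axial_n = 7,
                            tank_spacing_mm = 2) {
  structure(list(n_energy = n_energy, e_min_MeV = e_min_MeV,
                 e_max_MeV = e_max_MeV, sample_spacing_mm = sample_spacing_mm,
                 tank_axial_n = tank_axial_n, tank_spacing_mm = tank_spacing_mm),
            class = "forward_control")
}

# lattice of sample centers (k + 0.5) * spacing inside [lo, hi)
.lattice_1d <- function(lo, hi, spacing) {
  k <- seq(floor(lo / spacing) - 1, ceiling(hi / spacing) + 1)
  c0 <- (k + 0.5) * spacing
  c0[c0 >= lo - 1e-9 & c0 < hi - 1e-9]
}

.region_points <- function(region, spacing) {
  x <- .lattice_1d(region$cx_mm - region$w_mm / 2,
                   region$cx_mm + region$w_mm / 2, spacing)
  z <- .lattice_1d(region$cz_mm - region$h_mm / 2,
                   region$cz_mm + region$h_mm / 2, spacing)
  if (!length(x) || !length(z)) {
    stop(sprintf("region '%s' contains no sample points", region$label),
         call. = FALSE)
  }
  list(x = rep(x, times = length(z)), z = rep(z, each = length(x)))
}

# Precompute everything model-independent for a set of (plane, points):
# surviving energy nodes, trapezoid weights x stopping power x unit
# conversion, magnet displacement, and the angle matrix (points x energy).
.plane_context <- function(geometry, z_mm, x_pts, z_pts, control) {
  tab <- geometry$sp_table
  e_max <- min(control$e_max_MeV, max(tab$energies_MeV))
  e <- exp(seq(log(control$e_min_MeV), log(e_max),
               length.out = control$n_energy))
  w <- numeric(length(e))
  de <- diff(e)
  w[-1] <- w[-1] + de / 2
  w[-length(e)] <- w[-length(e)] + de / 2

  t_up <- .upstream_areal(geometry, z_mm)
  e_p <- degrade_energy(tab, e, t_up)
  surv <- e_p > tab$e_cutoff_MeV

  d_mm <- rep(0, length(e))
  for (mag in .geometry_magnets(geometry)) {
    if (mag$field_T <= 0 || z_mm <= mag$position_mm + mag$length_mm) next
    t_mag <- .upstream_areal(geometry, mag$position_mm)
    e_mag <- degrade_energy(tab, e, t_mag)
    ok <- e_mag > 0
    d_mag <- rep(Inf, length(e))
    d_mag[ok] <- magnet_deflection(mag, e_mag[ok],
                                   drift_mm = z_mm - (mag$position_mm + mag$length_mm))
    d_mm <- d_mm + d_mag
    surv <- surv & is.finite(d_mm)
  }
  if (!any(surv)) {
    return(list(empty = TRUE, n_pts = length(x_pts)))
  }
  e_s <- e[surv]
  z_cm <- z_mm / 10
  ws <- w[surv] * stopping_power(tab, e_p[surv]) *
    .const$MeV_per_g_to_Gy / z_cm^2
  # signed polar angle (deg) of the straight-line emission direction that
  # lands at (x, z) on the plane after the magnet displacement d_mm
  ax <- atan(outer(x_pts, d_mm[surv], "-") / z_mm) * 180 / pi
  az <- atan(z_pts / z_mm) * 180 / pi
  a <- sign(ax) * sqrt(ax^2 + az^2)
  list(empty = FALSE, energy = e_s, wS = ws, angle = a, n_pts = length(x_pts))
}

# dose (Gy) at each precomputed point for a given spectrum model
.context_dose <- function(model, ctx) {
  if (ctx$empty) return(rep(0, ctx$n_pts))
  spec <- model$lambda * exp(-ctx$energy / model$t1) +
    (1 - model$lambda) * exp(-ctx$energy / model$t2)
  ang <- exp(-((ctx$angle - model$alpha0) / model$delta_alpha)^2)
  as.numeric(model$n0 * (ang %*% (spec * ctx$wS)))
}

.plane_z <- function(geometry, plane_label) {
  i <- match(plane_label, geometry$planes$label)
  if (is.na(i)) {
    stop(sprintf("no plane labelled '%s' in geometry", plane_label), call. = FALSE)
  }
  geometry$planes$position_mm[i]
}

#' Forward-modeled mean dose in a film region
#'
#' Deterministic water-equivalent CSDA forward model: the two-temperature
#' spectrum is degraded through every slab upstream of the detector plane
#' (electrons whose CSDA range is exhausted are removed), deflected by
#' the hard-edge cleaning magnet, converted from planar fluence to dose
#' via the water stopping power at the local energy, and averaged over a
#' sampling lattice inside the region. Linear in the spectrum
#' normalization `n0` and additive over disjoint energy bands.
#'
#' @param model An [electron_spectrum()].
#' @param geometry A [beamline_geometry()].
#' @param plane_label Label of a detector plane in `geometry$planes`.
#' @param region One-row data frame with `label`, `cx_mm`, `cz_mm`,
#'   `w_mm`, `h_mm` (see [region_spec()]).
#' @param control A [forward_control()].
#' @return Mean dose (Gy) over the region.
#' @export
forward_dose <- function(model, geometry, plane_label, region,
                         control = forward_control()) {
  stopifnot(inherits(model, "electron_spectrum"),
            inherits(geometry, "beamline_geometry"))
  region <- as.list(tibble::as_tibble(region)[1, ])
  z_mm <- .plane_z(geometry, plane_label)
  pts <- .region_points(region, control$sample_spacing_mm)
  ctx <- .plane_context(geometry, z_mm, pts$x, pts$z, control)
  mean(.context_dose(model, ctx))
}

#' Forward-modeled doses for a table of regions
#'
#' Vectorized version of [forward_dose()] over a regions table (columns
#' `label`, `plane`, `cx_mm`, `cz_mm`, `w_mm`, `h_mm`); plane-level
#' transport quantities are computed once per plane.
#'
#' @inheritParams forward_dose
#' @param regions Regions data frame.
#' @return The input tibble with a `modeled_Gy` column appended.
#' @export
forward_region_doses <- function(model, geometry, regions,
                                 control = forward_control()) {
  ctx <- build_forward_context(geometry, regions, control)
  dplyr::mutate(tibble::as_tibble(regions),
                modeled_Gy = evaluate_forward_context(model, ctx))
}

#' Precompiled forward-model context for repeated evaluation
#'
#' Splits the model-independent transport work (energy degradation,
#' magnet dispersion, angle geometry) from the model-dependent spectrum
#' evaluation so that an optimizer can call the forward model thousands
#' of times cheaply. Used internally by [fit_spectrum()].
#'
#' @inheritParams forward_region_doses
#' @return An opaque context object for [evaluate_forward_context()].
#' @export
build_forward_context <- function(geometry, regions,
                                  control = forward_control()) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("label", "plane", "cx_mm", "cz_mm", "w_mm", "h_mm")
                %in% names(regions)))
  planes <- split(seq_len(nrow(regions)), regions$plane)
  ctxs <- lapply(names(planes), function(pl) {
    idx <- planes[[pl]]
    pts <- lapply(idx, function(i)
      .region_points(as.list(regions[i, ]), control$sample_spacing_mm))
    n_per <- vapply(pts, function(p) length(p$x), integer(1))
    ctx <- .plane_context(geometry, .plane_z(geometry, pl),
                          unlist(lapply(pts, `[[`, "x")),
                          unlist(lapply(pts, `[[`, "z")), control)
    list(ctx = ctx, idx = idx, groups = rep(seq_along(idx), times = n_per))
  })
  list(plane_ctxs = ctxs, n_regions = nrow(regions), labels = regions$label)
}

#' @rdname build_forward_context
#' @param model An [electron_spectrum()].
#' @param context Result of [build_forward_context()].
#' @return Numeric vector of modeled region doses (Gy), in region order.
#' @export
evaluate_forward_context <- function(model, context) {
  out <- numeric(context$n_regions)
  for (pc in context$plane_ctxs) {
    d <- .context_dose(model, pc$ctx)
    out[pc$idx] <- as.numeric(tapply(d, pc$groups, mean))
  }
  out
}

#' Volume-averaged dose inside the water tank
#'
#' Averages the forward-modeled dose over an axial x transverse grid in
#' the tank water, restricted transversely to the sensor-relevant central
#' column (`sample_width_mm` x `sample_height_mm` of the tank
#' definition). For a beam that only degrades with depth the result is
#' bracketed by the entrance- and exit-plane doses.
#'
#' @inheritParams forward_dose
#' @return Mean dose (Gy) in the tank sampling volume.
#' @export
tank_mean_dose <- function(model, geometry, control = forward_control()) {
  stopifnot(inherits(model, "electron_spectrum"),
            inherits(geometry, "beamline_geometry"))
  tank <- geometry$tank
  if (is.null(tank)) stop("geometry has no tank", call. = FALSE)
  depths <- tank$entrance_mm +
    tank$length_mm * (seq_len(control$tank_axial_n) - 0.5) / control$tank_axial_n
  box <- list(label = "tank", cx_mm = 0, cz_mm = 0,
              w_mm = tank$sample_width_mm %||% tank$width_mm,
              h_mm = tank$sample_height_mm %||% tank$height_mm)
  pts <- .region_points(box, control$tank_spacing_mm)
  plane_means <- vapply(depths, function(z_mm) {
    ctx <- .plane_context(geometry, z_mm, pts$x, pts$z, control)
    mean(.context_dose(model, ctx))
  }, numeric(1))
  mean(plane_means)
}

#' Energy bookkeeping through the slab stack
#'
#' Tracks, for the on-axis spectrum integrated over an energy band, the
#' energy entering the stack, the energy deposited in each slab (CSDA
#' loss, including electrons stopped inside), and the energy carried by
#' electrons exiting the last slab. Deposited plus exiting equals
#' injected by construction of the continuous-slowing-down model; the
#' audit makes the invariant checkable.
#'
#' @inheritParams forward_dose
#' @param solid_angle_sr Solid angle used to weight the spectrum (sr).
#' @return A tibble with one row per slab plus `injected` and `exiting`
#'   attributes (MeV per steradian-normalized beam).
#' @export
transport_energy_audit <- function(model, geometry, solid_angle_sr = 0.16,
                                   control = forward_control()) {
  tab <- geometry$sp_table
  e_max <- min(control$e_max_MeV, max(tab$energies_MeV))
  e <- exp(seq(log(control$e_min_MeV), log(e_max),
               length.out = control$n_energy))
  w <- numeric(length(e)); de <- diff(e)
  w[-1] <- w[-1] + de / 2; w[-length(e)] <- w[-length(e)] + de / 2
  n_e <- eval_spectrum(model, e, model$alpha0) * w * solid_angle_sr

  ly <- geometry$layers
  e_cur <- e
  dep <- numeric(nrow(ly))
  for (i in seq_len(nrow(ly))) {
    t_i <- ly$thickness_mm[i] * ly$density_g_cm3[i] / 10
    e_next <- degrade_energy(tab, e_cur, t_i)
    dep[i] <- sum(n_e * (e_cur - e_next))
    e_cur <- e_next
  }
  out <- tibble::tibble(name = ly$name, deposited_MeV = dep)
  attr(out, "injected_MeV") <- sum(n_e * e)
  attr(out, "exiting_MeV") <- sum(n_e * e_cur)
  out
}
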