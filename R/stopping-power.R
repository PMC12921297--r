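#' Stopping-power table
#'
#' Total mass stopping power of electrons in a material on a strictly
#' increasing energy grid. Interpolation between grid points is log-log
#' linear (exact at the nodes, no extrapolation). On construction a fine
#' cumulative CSDA-range grid is precomputed so that [csda_range()] and
#' [degrade_energy()] are fast and mutually consistent.
#'
#' Below the low-energy integration cutoff (`e_cutoff_MeV`, default
#' 0.01 MeV) the residual range is approximated as `E_cut / S(E_cut)` and
#' electrons are treated as stopped (their remaining energy is deposited
#' locally).
#'
#' @param energies_MeV Strictly increasing kinetic energies (MeV); at
#'   least 10 points, spanning at least \[0.1, 100\] MeV.
#' @param total_sp Total mass stopping power (MeV cm^2/g), all positive.
#' @param material Label.
#' @param e_cutoff_MeV Low-energy cutoff for the range integral.
#' @return An object of class `stopping_power_table`.
#' @export
stopping_power_table <- function(energies_MeV, total_sp, material = "custom",
                                 e_cutoff_MeV = 0.01) {
  stopifnot(length(energies_MeV) == length(total_sp))
  if (length(energies_MeV) < 10) stop("need at least 10 grid points", call. = FALSE)
  if (any(diff(energies_MeV) <= 0)) stop("energies must be strictly increasing", call. = FALSE)
  if (any(total_sp <= 0)) stop("stopping powers must be positive", call. = FALSE)
  if (min(energies_MeV) > 0.1 || max(energies_MeV) < 100) {
    stop("table must span at least [0.1, 100] MeV", call. = FALSE)
  }
  e_cutoff_MeV <- max(e_cutoff_MeV, min(energies_MeV))
  obj <- structure(
    list(energies_MeV = as.numeric(energies_MeV),
         total_sp = as.numeric(total_sp),
         material = material,
         e_cutoff_MeV = e_cutoff_MeV),
    class = "stopping_power_table"
  )
  obj$range_grid <- .build_range_grid(obj)
  obj
}

# Fine grid of cumulative ranges: R(E) = E_cut/S(E_cut) + int_{E_cut}^E dE'/S.
# Trapezoid rule on a log-spaced grid merged with the table nodes; the grid
# is dense enough (~4000 pts) that the quadrature error is < 1e-6 relative.
.build_range_grid <- function(tab, n = 4000) {
  e_lo <- tab$e_cutoff_MeV
  e_hi <- max(tab$energies_MeV)
  e <- sort(unique(c(exp(seq(log(e_lo), log(e_hi), length.out = n)),
                     tab$energies_MeV[tab$energies_MeV >= e_lo])))
  inv_s <- 1 / .sp_interp(tab, e)
  seg <- diff(e) * (inv_s[-1] + inv_s[-length(inv_s)]) / 2
  r0 <- e_lo / .sp_interp(tab, e_lo)
  list(energy = e, range = r0 + c(0, cumsum(seg)), r_cut = r0)
}

# log-log interpolation, no extrapolation checks here (callers validate)
.sp_interp <- function(tab, energy) {
  exp(stats::approx(log(tab$energies_MeV), log(tab$total_sp),
                    xout = log(energy), rule = 1)$y)
}

.check_in_range <- function(tab, energy) {
  if (any(energy < min(tab$energies_MeV) | energy > max(tab$energies_MeV))) {
    stop(sprintf("energy outside table range [%g, %g] MeV (no extrapolation)",
                 min(tab$energies_MeV), max(tab$energies_MeV)), call. = FALSE)
  }
}

#' @export
print.stopping_power_table <- function(x, ...) {
  cat(sprintf("<stopping_power_table> %s: %d points, %g-%g MeV\n",
              x$material, length(x$energies_MeV),
              min(x$energies_MeV), max(x$energies_MeV)))
  invisible(x)
}

#' Read a stopping-power table from CSV
#'
#' Two-column CSV (`energy_MeV`, `total_sp_MeV_cm2_g`) with `#` comments;
#' a `# material=...` comment line sets the label.
#'
#' @param path File path.
#' @inheritParams stopping_power_table
#' @return A [stopping_power_table()].
#' @export
read_stopping_power <- function(path, e_cutoff_MeV = 0.01) {
  lines <- readLines(path)
  material <- "unknown"
  m <- grep("^#\\s*material=", lines, value = TRUE)
  if (length(m)) material <- sub("^#\\s*material=\\s*", "", m[1])
  df <- utils::read.csv(text = lines, comment.char = "#")
  stopping_power_table(df[[1]], df[[2]], material = material,
                       e_cutoff_MeV = e_cutoff_MeV)
}

#' Packaged water-equivalent stopping-power tables
#'
#' @param material `"water"` (default transport table) or `"mylar"`
#'   (independent second tabulation, used for cross-checks).
#' @return A [stopping_power_table()].
#' @export
default_stopping_power <- function(material = c("water", "mylar")) {
  material <- match.arg(material)
  path <- system.file("extdata", paste0("stopping_power_", material, ".csv"),
                      package = "flashrecon", mustWork = TRUE)
  read_stopping_power(path)
}

#' Interpolated total mass stopping power
#'
#' @param table A [stopping_power_table()].
#' @param energy Kinetic energy (MeV), within the table range; vectorized.
#' @return Stopping power (MeV cm^2/g).
#' @export
stopping_power <- function(table, energy) {
  stopifnot(inherits(table, "stopping_power_table"))
  .check_in_range(table, energy)
  .sp_interp(table, energy)
}

#' CSDA range
#'
#' Continuous-slowing-down range `R(E) = R_cut + int_{E_cut}^{E} dE'/S(E')`
#' in areal density, with the sub-cutoff residual approximated as
#' `E_cut/S(E_cut)`. Strictly increasing in energy.
#'
#' @inheritParams stopping_power
#' @return Range (g/cm^2).
#' @export
csda_range <- function(table, energy) {
  stopifnot(inherits(table, "stopping_power_table"))
  .check_in_range(table, energy)
  rg <- table$range_grid
  out <- stats::approx(rg$energy, rg$range, xout = pmax(energy, table$e_cutoff_MeV),
                       rule = 2)$y
  out[energy <= table$e_cutoff_MeV] <- energy[energy <= table$e_cutoff_MeV] /
    .sp_interp(table, table$e_cutoff_MeV)
  out
}

#' Degrade electron energy through a slab
#'
#' Solves `dE/dx = -S(E)` through a slab of the given areal density via
#' the precomputed range grid: `E_out = R^{-1}(R(E_in) - t)`. Returns 0
#' (stopped, energy deposited locally) when the slab exhausts the CSDA
#' range or leaves the electron below the low-energy cutoff. Traversing
#' two slabs sequentially is identical to traversing their sum.
#'
#' @inheritParams stopping_power
#' @param energy_in Incident kinetic energy (MeV), within table range.
#' @param areal_density_g_cm2 Slab areal density (g/cm^2), >= 0; scalar.
#' @return Exit kinetic energy (MeV); 0 if stopped.
#' @export
degrade_energy <- function(table, energy_in, areal_density_g_cm2) {
  stopifnot(inherits(table, "stopping_power_table"))
  live_in <- energy_in > 0  # zeros pass through as already-stopped
  .check_in_range(table, energy_in[live_in])
  if (areal_density_g_cm2 < 0) stop("areal density must be >= 0", call. = FALSE)
  if (areal_density_g_cm2 == 0) return(energy_in)
  rg <- table$range_grid
  out <- numeric(length(energy_in))
  if (any(live_in)) {
    r_out <- csda_range(table, energy_in[live_in]) - areal_density_g_cm2
    alive <- r_out > rg$r_cut
    val <- numeric(sum(live_in))
    if (any(alive)) {
      val[alive] <- stats::approx(rg$range, rg$energy, xout = r_out[alive],
                                  rule = 2)$y
    }
    out[live_in] <- val
  }
  out
}
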