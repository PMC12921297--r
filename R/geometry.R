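#' Beamline geometry
#'
#' Ordered material slabs along the beam axis, an optional cleaning
#' magnet, named detector planes, and the sealed water tank. Axial
#' coordinates are mm from the foam target along the laser axis; the
#' transverse plane uses x for the (horizontal) magnet deflection
#' direction and z vertical, origin on the beam axis. All slabs are
#' treated as water-equivalent: energy loss uses a single stopping-power
#' table scaled by each layer's physical density.
#'
#' @param layers Data frame with columns `name`, `position_mm` (slab
#'   entrance), `thickness_mm`, `density_g_cm3`; rows ordered by position,
#'   non-overlapping.
#' @param planes Data frame with columns `label`, `position_mm`; planes
#'   must not fall strictly inside a slab other than at its boundary
#'   (the water tank interior is exempt: virtual planes inside the water
#'   are what [tank_mean_dose()] averages over).
#' @param magnet A [magnet_block()], a list of them (beamlines with a
#'   cleaning magnet before the tank and a dispersive magnet behind it),
#'   or `NULL`.
#' @param tank List with `entrance_mm`, `length_mm`, `width_mm`,
#'   `height_mm`, and the transverse averaging box `sample_width_mm`,
#'   `sample_height_mm` (the sensor-relevant central column).
#' @param sp_table A [stopping_power_table()].
#' @return An object of class `beamline_geometry`.
#' @export
beamline_geometry <- function(layers, planes, magnet = NULL, tank = NULL,
                              sp_table = default_stopping_power()) {
  layers <- tibble::as_tibble(layers)
  planes <- tibble::as_tibble(planes)
  stopifnot(all(c("name", "position_mm", "thickness_mm", "density_g_cm3")
                %in% names(layers)),
            all(c("label", "position_mm") %in% names(planes)))
  if (any(layers$thickness_mm < 0) || any(layers$density_g_cm3 <= 0)) {
    stop("layer thicknesses must be >= 0 and densities > 0", call. = FALSE)
  }
  if (is.unsorted(layers$position_mm, strictly = TRUE)) {
    stop("layer positions must be strictly increasing", call. = FALSE)
  }
  ends <- layers$position_mm + layers$thickness_mm
  if (any(layers$position_mm[-1] < ends[-length(ends)] - 1e-9)) {
    stop("layers overlap", call. = FALSE)
  }
  water <- which(layers$name == "water")
  for (p in planes$position_mm) {
    inside <- which(p > layers$position_mm + 1e-9 & p < ends - 1e-9)
    if (length(setdiff(inside, water))) {
      stop(sprintf("plane at %g mm lies inside slab '%s'",
                   p, layers$name[setdiff(inside, water)[1]]), call. = FALSE)
    }
  }
  structure(list(layers = layers, planes = planes, magnet = magnet,
                 tank = tank, sp_table = sp_table),
            class = "beamline_geometry")
}

#' @export
print.beamline_geometry <- function(x, ...) {
  cat("<beamline_geometry>\n")
  cat(sprintf("  %d layers, %d planes (%s)\n", nrow(x$layers), nrow(x$planes),
              paste(x$planes$label, collapse = ", ")))
  for (m in .geometry_magnets(x)) {
    cat(sprintf("  magnet: %.2f T, %g mm long at %g mm\n",
                m$field_T, m$length_mm, m$position_mm))
  }
  if (!is.null(x$tank)) {
    cat(sprintf("  tank: water %g-%g mm, cross-section %gx%g mm\n",
                x$tank$entrance_mm, x$tank$entrance_mm + x$tank$length_mm,
                x$tank$width_mm, x$tank$height_mm))
  }
  invisible(x)
}

#' Packaged default beamline
#'
#' Reproduces the irradiation setup: a protective layer (150 um Al foil
#' plus three radiochromic films) at 20 mm from the target, a 0.4 T
#' cleaning magnet at 30 mm, film RCF#1 in front of the sealed tank, 2 mm
#' PEEK tank walls enclosing 30 mm of water, film RCF#2 directly behind
#' the tank, and film RCF#3 behind an additional 0.4 T dispersive magnet
#' (which is what turns RCF#3 into an energy-dispersed plane and gives
#' the six-region reconstruction its spectral leverage). Exact axial
#' positions of RCF#2/RCF#3 and the tank are not published; the values
#' here are documented package assumptions. The cleaning magnet's
#' effective length (10 mm) is likewise an assumption chosen so that the
#' deflection of the multi-MeV beam is a few mm at the films — large
#' enough to see, small enough that the on-axis tank is irradiated.
#'
#' @param sp_table Stopping-power table; default water.
#' @return A [beamline_geometry()].
#' @export
default_beamline <- function(sp_table = default_stopping_power()) {
  layers <- tibble::tribble(
    ~name,          ~position_mm, ~thickness_mm, ~density_g_cm3,
    "al_foil",      20,           0.15,          2.70,
    "rcf_protect",  20.15,        0.375,         1.35,
    "rcf1",         50,           0.125,         1.35,
    "peek_front",   52,           2,             1.32,
    "water",        54,           30,            1.00,
    "peek_back",    84,           2,             1.32,
    "rcf2",         87,           0.125,         1.35
  )
  planes <- tibble::tribble(
    ~label,          ~position_mm,
    "RCF1",          50,
    "tank_entrance", 54,
    "RCF2",          87,
    "RCF3",          125
  )
  beamline_geometry(
    layers, planes,
    magnet = list(
      magnet_block(field_T = 0.4, length_mm = 10, position_mm = 30),
      magnet_block(field_T = 0.4, length_mm = 30, position_mm = 89)
    ),
    tank = list(entrance_mm = 54, length_mm = 30, width_mm = 20,
                height_mm = 20, sample_width_mm = 5, sample_height_mm = 5),
    sp_table = sp_table
  )
}

# geometry$magnet may be a single magnet_block or a list of them
.geometry_magnets <- function(geometry) {
  m <- geometry$magnet
  if (is.null(m)) return(list())
  if (inherits(m, "magnet_block")) list(m) else m
}

# water-equivalent areal density (g/cm^2) of all slab material strictly
# upstream of axial position z_mm (partial water layers count pro rata)
.upstream_areal <- function(geometry, z_mm) {
  ly <- geometry$layers
  part <- pmax(0, pmin(z_mm - ly$position_mm, ly$thickness_mm))
  sum(part * ly$density_g_cm3 / 10)
}

#' Write / read a beamline geometry as YAML
#'
#' Plain-text round-trip of layers, magnet, planes and tank; the
#' stopping-power table is referenced by its material label and reloaded
#' from the packaged tables.
#'
#' @param geometry A [beamline_geometry()].
#' @param path File path.
#' @return `read_geometry()` returns a [beamline_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "beamline_geometry"))
  x <- list(
    layers = lapply(seq_len(nrow(geometry$layers)), function(i)
      as.list(geometry$layers[i, ])),
    planes = lapply(seq_len(nrow(geometry$planes)), function(i)
      as.list(geometry$planes[i, ])),
    magnets = lapply(.geometry_magnets(geometry), unclass),
    tank = geometry$tank,
    stopping_power_material = geometry$sp_table$material
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  x <- yaml::read_yaml(path)
  mat <- x$stopping_power_material %||% "water"
  sp <- if (mat %in% c("water", "mylar")) default_stopping_power(mat)
        else default_stopping_power()
  beamline_geometry(
    layers = dplyr::bind_rows(lapply(x$layers, tibble::as_tibble)),
    planes = dplyr::bind_rows(lapply(x$planes, tibble::as_tibble)),
    magnet = if (length(x$magnets))
      lapply(x$magnets, function(m)
        magnet_block(m$field_T, m$length_mm, m$position_mm)),
    tank = x$tank,
    sp_table = sp
  )
}
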