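#' Gridded 2D dose map
#'
#' A scanned (or simulated) radiochromic film as a regular grid of doses.
#' Columns run along the transverse x axis (magnet deflection direction),
#' rows along z (vertical); the pixel centered at `[i, j]` sits at
#' `x = origin[1] + (j - 0.5) * pixel_size`,
#' `z = origin[2] + (i - 0.5) * pixel_size`.
#'
#' @param values Numeric matrix of doses (Gy), all finite and >= 0.
#' @param pixel_size_mm Pixel pitch (mm), > 0.
#' @param origin_mm Length-2 numeric, (x, z) of the grid corner (mm).
#' @param plane Plane label (e.g. `"RCF2"`).
#' @return An object of class `dose_map`.
#' @export
dose_map <- function(values, pixel_size_mm = 0.25, origin_mm = c(0, 0),
                     plane = "RCF") {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("dose values must be finite", call. = FALSE)
  if (any(values < 0)) stop("dose values must be >= 0", call. = FALSE)
  if (pixel_size_mm <= 0) stop("`pixel_size_mm` must be positive", call. = FALSE)
  structure(list(values = values, pixel_size_mm = pixel_size_mm,
                 origin_mm = as.numeric(origin_mm), plane = plane),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %s: %d x %d px @ %g mm, origin (%g, %g) mm, %0.3g-%0.3g Gy\n",
              x$plane, nrow(x$values), ncol(x$values), x$pixel_size_mm,
              x$origin_mm[1], x$origin_mm[2], min(x$values), max(x$values)))
  invisible(x)
}

# pixel center coordinates
.map_x <- function(map) map$origin_mm[1] + (seq_len(ncol(map$values)) - 0.5) * map$pixel_size_mm
.map_z <- function(map) map$origin_mm[2] + (seq_len(nrow(map$values)) - 0.5) * map$pixel_size_mm

#' Write / read a dose map as plain text
#'
#' Header lines `# pixel_size_mm=`, `# origin_mm=x,z`, `# plane=` followed
#' by whitespace-separated rows of doses at 6 significant digits; a
#' write-read round trip reproduces the printed values exactly.
#'
#' @param map A [dose_map()].
#' @param path File path.
#' @return `read_dose_map()` returns a [dose_map()]; `write_dose_map()`
#'   returns `path` invisibly.
#' @export
write_dose_map <- function(map, path) {
  stopifnot(inherits(map, "dose_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pixel_size_mm=%.10g", map$pixel_size_mm),
    sprintf("# origin_mm=%.10g,%.10g", map$origin_mm[1], map$origin_mm[2]),
    sprintf("# plane=%s", map$plane)
  ), con)
  writeLines(apply(map$values, 1, function(r)
    paste(sprintf("%.6g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_dose_map
#' @export
read_dose_map <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty dose-map file: ", path, call. = FALSE)
  hdr <- grep("^#", lines)
  get <- function(key) {
    i <- grep(paste0("^#\\s*", key, "="), lines)
    if (!length(i)) {
      stop(sprintf("malformed header: missing '%s' (line %d)", key,
                   length(hdr) + 1L), call. = FALSE)
    }
    sub(paste0("^#\\s*", key, "=\\s*"), "", lines[i[1]])
  }
  px <- suppressWarnings(as.numeric(get("pixel_size_mm")))
  origin <- suppressWarnings(as.numeric(strsplit(get("origin_mm"), ",")[[1]]))
  plane <- get("plane")
  if (!isTRUE(px > 0) || length(origin) != 2 || any(is.na(origin))) {
    stop("malformed header values in ", path, call. = FALSE)
  }
  body <- setdiff(seq_along(lines), hdr)
  body <- body[nzchar(trimws(lines[body]))]
  if (!length(body)) stop("dose-map file has no data rows: ", path, call. = FALSE)
  rows <- lapply(seq_along(body), function(k) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[body[k]]), "\\s+")[[1]]))
    if (any(is.na(v))) stop(sprintf("non-numeric dose at line %d", body[k]), call. = FALSE)
    if (any(v < 0)) stop(sprintf("negative dose at line %d", body[k]), call. = FALSE)
    v
  })
  if (length(unique(lengths(rows))) != 1) {
    stop("ragged rows in dose-map file: ", path, call. = FALSE)
  }
  dose_map(do.call(rbind, rows), pixel_size_mm = px, origin_mm = origin,
           plane = plane)
}

#' Rectangular named region on a film
#'
#' @param label Region label (e.g. `"area-1"`, `"blue-box"`).
#' @param cx_mm,cz_mm Region center (mm), transverse film coordinates.
#' @param w_mm,h_mm Width and height (mm), > 0.
#' @param plane Plane label the region belongs to.
#' @return A one-row tibble (regions tables are built by row-binding).
#' @export
region_spec <- function(label, cx_mm, cz_mm, w_mm = 5, h_mm = 5,
                        plane = "RCF2") {
  if (any(w_mm <= 0) || any(h_mm <= 0)) {
    stop("region width and height must be positive", call. = FALSE)
  }
  tibble::tibble(label = label, plane = plane, cx_mm = cx_mm, cz_mm = cz_mm,
                 w_mm = w_mm, h_mm = h_mm)
}

#' Packaged default reconstruction regions
#'
#' Six 5 x 5 mm regions, three on RCF#2 and three on RCF#3, straddling
#' the beam axis and the magnet-deflection side, plus the "blue box" (the
#' 5 x 5 mm projection of the tank volume) on each film. The exact region
#' centers used in the experiment are not published; these defaults are
#' package assumptions placed to sample both the angular wing and the
#' energy-dispersed side of the distribution.
#'
#' @param blue_box If `TRUE`, append the blue-box regions.
#' @return A regions tibble.
#' @export
default_regions <- function(blue_box = FALSE) {
  reg <- dplyr::bind_rows(
    region_spec("area-1", -5, 0, plane = "RCF2"),
    region_spec("area-2",  0, 0, plane = "RCF2"),
    region_spec("area-3",  6, 0, plane = "RCF2"),
    region_spec("area-4",  2, 0, plane = "RCF3"),
    region_spec("area-5", 10, 0, plane = "RCF3"),
    region_spec("area-6", 18, 0, plane = "RCF3")
  )
  if (blue_box) {
    reg <- dplyr::bind_rows(
      reg,
      region_spec("blue-box", 0, 0, plane = "RCF1"),
      region_spec("blue-box", 0, 0, plane = "RCF2")
    )
  }
  reg
}

#' Write / read region tables
#'
#' CSV with columns `label,plane,cx_mm,cz_mm,w_mm,h_mm`.
#'
#' @param regions Regions tibble.
#' @param path File path.
#' @export
write_regions <- function(regions, path) {
  utils::write.csv(tibble::as_tibble(regions), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}

# logical index of pixels whose centers fall in the region
# (half-open on the max side)
.pixels_in_region <- function(map, region) {
  x <- .map_x(map); z <- .map_z(map)
  in_x <- x >= region$cx_mm - region$w_mm / 2 - 1e-9 &
    x < region$cx_mm + region$w_mm / 2 - 1e-9
  in_z <- z >= region$cz_mm - region$h_mm / 2 - 1e-9 &
    z < region$cz_mm + region$h_mm / 2 - 1e-9
  list(rows = which(in_z), cols = which(in_x))
}

#' Region mean dose and relative deviation
#'
#' Mean over pixels whose centers fall inside the region (boundaries
#' half-open on the max side) and the relative deviation, defined as half
#' the peak-to-peak spread over the mean, `(max - min) / (2 * mean)` — a
#' uniform map has deviation 0.
#'
#' @param map A [dose_map()].
#' @param region One-row region (see [region_spec()]).
#' @return A one-row tibble: `label`, `n_pixels`, `mean_Gy`, `rel_dev`.
#' @export
region_stats <- function(map, region) {
  stopifnot(inherits(map, "dose_map"))
  region <- as.list(tibble::as_tibble(region)[1, ])
  px <- .pixels_in_region(map, region)
  if (!length(px$rows) || !length(px$cols)) {
    stop(sprintf("region '%s' overlaps no pixel centers", region$label),
         call. = FALSE)
  }
  v <- map$values[px$rows, px$cols]
  m <- mean(v)
  tibble::tibble(label = region$label, n_pixels = length(v), mean_Gy = m,
                 rel_dev = if (m > 0) (max(v) - min(v)) / (2 * m) else 0)
}

#' Mean dose in the tank-projection "blue box"
#'
#' The 5 x 5 mm region of film corresponding to the projection of the
#' water tank's inner volume; delegates to [region_stats()].
#'
#' @param map A [dose_map()].
#' @param tank_projection Region; default a 5 x 5 mm box centered on the
#'   beam axis.
#' @return Mean dose (Gy).
#' @export
blue_box_mean <- function(map,
                          tank_projection = region_spec("blue-box", 0, 0, 5, 5)) {
  region_stats(map, tank_projection)$mean_Gy
}

#' Two-compartment average dose
#'
#' Average of the doses in the two film compartments flanking the
#' measurement volume, `D_av = (D1 + D2) / 2`, reported both at full
#' precision and rounded to integer Gy (half away from zero).
#'
#' @param d1_Gy,d2_Gy Compartment doses (Gy), >= 0.
#' @return A one-row tibble: `d_av_Gy`, `d_av_reported_Gy`.
#' @export
#' @examples
#' two_compartment_average(85, 70) # 77.5 -> 78
two_compartment_average <- function(d1_Gy, d2_Gy) {
  if (any(d1_Gy < 0) || any(d2_Gy < 0)) stop("doses must be >= 0", call. = FALSE)
  av <- (d1_Gy + d2_Gy) / 2
  tibble::tibble(d_av_Gy = av, d_av_reported_Gy = round_half_away(av, 0))
}

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (the convention used for
#' reported doses and slopes), unlike base R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
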