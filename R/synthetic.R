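#' Noise configuration for synthetic shots
#'
#' Defaults reflect the measured spread of the experimental data: 5-20%
#' relative dose deviation behind the tank (10% field amplitude), 10-40%
#' in front (25%), 7-10% oxygen-meter noise (8%), and a ~10 Gy X-ray
#' background on the front film attenuated to ~1 Gy behind the tank.
#'
#' @param region_rel Log-normal spatial noise amplitude behind the tank.
#' @param front_rel Spatial noise amplitude on the front film.
#' @param sensor_rel Oxygen-meter relative noise.
#' @param xray_front_Gy,xray_behind_Gy X-ray background doses (Gy).
#' @param corr_mm Correlation length of the spatial noise field (mm).
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(region_rel = 0.10, front_rel = 0.25,
                         sensor_rel = 0.08, xray_front_Gy = 10,
                         xray_behind_Gy = 1, corr_mm = 2) {
  structure(list(region_rel = region_rel, front_rel = front_rel,
                 sensor_rel = sensor_rel, xray_front_Gy = xray_front_Gy,
                 xray_behind_Gy = xray_behind_Gy, corr_mm = corr_mm),
            class = "noise_config")
}

#' @rdname noise_config
#' @export
zero_noise <- function() {
  noise_config(region_rel = 0, front_rel = 0, sensor_rel = 0,
               xray_front_Gy = 0, xray_behind_Gy = 0)
}

#' Default synthetic-truth spectrum
#'
#' The generating spectrum for synthetic shots: normalization chosen so
#' single-shot in-tank doses land in the experimental 20-50 Gy range,
#' temperatures in the measured DLA band, divergence matching the
#' observed ~0.16 sr directed beam.
#'
#' @return An [electron_spectrum()].
#' @export
default_truth <- function() {
  electron_spectrum(n0 = 7e11, lambda = 0.35, t1 = 7, t2 = 14,
                    alpha0 = 0, delta_alpha = 13)
}

# deterministic, order-independent seed splitting: multiplicative-hash
# counter scheme (Knuth constant), one substream per (shot, stage)
split_seed <- function(global_seed, counter) {
  as.integer((as.double(global_seed) * 2654435761 + counter * 40503) %%
               2147483629) + 1L
}

# smooth multiplicative log-normal field on a map grid: Gaussian-filtered
# white noise (separable kernel), normalized to unit variance in log space
# then scaled to `rel`; mean-corrected so E[field] = 1
.lognormal_field <- function(nr, nc, pixel_mm, corr_mm, rel, seed) {
  if (rel <= 0) return(matrix(1, nr, nc))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sigma_px <- max(corr_mm / pixel_mm, 0.5)
  half <- ceiling(3 * sigma_px)
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  pad <- half
  g <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
              nr + 2 * pad, nc + 2 * pad)
  # separable convolution via row/column filtering
  g <- apply(g, 2, function(col) stats::filter(col, k, sides = 2))
  g <- t(apply(g, 1, function(row) stats::filter(row, k, sides = 2)))
  g <- g[(pad + 1):(pad + nr), (pad + 1):(pad + nc)]
  g <- (g - mean(g)) / stats::sd(g)
  sigma_log <- sqrt(log(1 + rel^2))
  exp(sigma_log * g - sigma_log^2 / 2)
}

#' Default synthetic dose-map frame
#'
#' @param plane Plane label. RCF3 sits behind the dispersive magnet, so
#'   its frame is shifted to the deflection side.
#' @return A zero-dose [dose_map()] covering a 36 x 12 mm film area at
#'   0.25 mm pixels (flatbed-scan resolution class).
#' @export
empty_dose_map <- function(plane = "RCF2") {
  x0 <- if (plane == "RCF3") -10 else -18
  dose_map(matrix(0, 48, 144), pixel_size_mm = 0.25,
           origin_mm = c(x0, -6), plane = plane)
}

# noiseless forward-model dose map on a map's pixel grid
.model_dose_map <- function(model, geometry, map, control) {
  x <- .map_x(map); z <- .map_z(map)
  pts_x <- rep(x, each = length(z))
  pts_z <- rep(z, times = length(x))
  ctx <- .plane_context(geometry, .plane_z(geometry, map$plane),
                        pts_x, pts_z, control)
  d <- .context_dose(model, ctx)
  dose_map(matrix(d, nrow = length(z), ncol = length(x)),
           pixel_size_mm = map$pixel_size_mm, origin_mm = map$origin_mm,
           plane = map$plane)
}

#' Generate one synthetic laser shot
#'
#' Builds the full record the analysis consumes: per-plane dose maps
#' (forward-model dose times a smooth multiplicative log-normal spatial
#' noise field, plus a uniform X-ray background), the six measured region
#' doses (computed from the maps, so they are consistent with them by
#' construction), front/behind backgrounds, and the oxygen-meter trace
#' driven by the true in-tank dose times the configured true yield.
#' Deterministic given `seed`; all substream seeds derive from it by a
#' fixed counter-based hash, so components are order-independent.
#'
#' @param truth Generating [electron_spectrum()].
#' @param geometry A [beamline_geometry()].
#' @param noise A [noise_config()].
#' @param seed Integer seed.
#' @param regions Regions tibble to summarize (default [default_regions()]).
#' @param true_yield_uM_Gy Oxygen-consumption yield driving the trace.
#' @param initial_o2_uM Pre-shot oxygen concentration (uM).
#' @param medium Medium label.
#' @param maps If `FALSE`, skip dose-map synthesis and draw region doses
#'   as forward-model means times independent log-normal factors
#'   (`region_rel`) — much faster for large campaigns.
#' @param shot_id Identifier.
#' @param group Optional target-group metadata row (see [target_groups()]).
#' @param control A [forward_control()].
#' @return An object of class `shot_record`.
#' @export
generate_shot <- function(truth, geometry = default_beamline(),
                          noise = noise_config(), seed = 1,
                          regions = default_regions(),
                          true_yield_uM_Gy = 0.35, initial_o2_uM = 270,
                          medium = "water", maps = TRUE, shot_id = "shot-1",
                          group = NULL, control = forward_control()) {
  stopifnot(inherits(truth, "electron_spectrum"),
            inherits(noise, "noise_config"))
  tank_dose <- tank_mean_dose(truth, geometry, control)

  dose_maps <- NULL
  if (maps) {
    planes <- unique(c("RCF1", regions$plane))
    dose_maps <- lapply(planes, function(pl) {
      frame <- empty_dose_map(pl)
      m <- .model_dose_map(truth, geometry, frame, control)
      rel <- if (pl == "RCF1") noise$front_rel else noise$region_rel
      fld <- .lognormal_field(nrow(m$values), ncol(m$values),
                              m$pixel_size_mm, noise$corr_mm, rel,
                              split_seed(seed, match(pl, planes)))
      bg <- if (pl == "RCF1") noise$xray_front_Gy else noise$xray_behind_Gy
      dose_map(m$values * fld + bg, m$pixel_size_mm, m$origin_mm, pl)
    })
    names(dose_maps) <- planes
    region_doses <- dplyr::bind_rows(lapply(seq_len(nrow(regions)), function(i) {
      st <- region_stats(dose_maps[[regions$plane[i]]], regions[i, ])
      dplyr::mutate(regions[i, ], dose_Gy = st$mean_Gy, rel_dev = st$rel_dev)
    }))
  } else {
    mod <- forward_region_doses(truth, geometry, regions, control)
    old <- .Random.seed_save()
    set.seed(split_seed(seed, 11L))
    sigma_log <- sqrt(log(1 + noise$region_rel^2))
    fac <- if (noise$region_rel > 0) {
      exp(stats::rnorm(nrow(regions), sd = sigma_log) - sigma_log^2 / 2)
    } else rep(1, nrow(regions))
    .Random.seed_restore(old)
    region_doses <- dplyr::mutate(
      regions, dose_Gy = mod$modeled_Gy * fac + noise$xray_behind_Gy,
      rel_dev = noise$region_rel)
  }

  trace <- sensor_response(
    true_drop_uM = o2_drop_from_dose(tank_dose, true_yield_uM_Gy, initial_o2_uM),
    initial_o2_uM = initial_o2_uM, noise_rel = noise$sensor_rel,
    seed = split_seed(seed, 7L), medium = medium)

  structure(list(shot_id = shot_id, group = group, truth = truth,
                 dose_maps = dose_maps, region_doses = region_doses,
                 backgrounds = list(front_Gy = noise$xray_front_Gy,
                                    behind_Gy = noise$xray_behind_Gy),
                 o2_trace = trace, tank_dose_true_Gy = tank_dose,
                 true_yield_uM_Gy = true_yield_uM_Gy, medium = medium,
                 seed = seed),
            class = "shot_record")
}

#' @export
print.shot_record <- function(x, ...) {
  cat(sprintf("<shot_record> %s (%s, seed %d): true tank dose %.1f Gy, %d regions%s\n",
              x$shot_id, x$medium, x$seed, x$tank_dose_true_Gy,
              nrow(x$region_doses),
              if (is.null(x$dose_maps)) "" else
                sprintf(", maps: %s", paste(names(x$dose_maps), collapse = "/"))))
  invisible(x)
}

#' Target groups of the irradiation campaign
#'
#' Foam-target and nanosecond-pulse parameters of the five shot groups
#' (density and thickness of the CHO foam, duration/intensity/delay of
#' the pre-ionizing ns pulse); thickness ranges are represented by their
#' midpoints.
#'
#' @return A tibble with one row per group.
#' @export
target_groups <- function() {
  tibble::tribble(
    ~group, ~density_mg_cm3, ~thickness_um, ~ns_duration_ns,
    ~ns_intensity_1e13_W_cm2, ~delay_ns,
    1L, 2, 400,  3, 1, 3,
    2L, 2, 900,  3, 3, 3,
    3L, 5, 500,  3, 7, 5,
    4L, 3, 650,  3, 3, 3,
    5L, 2, 1500, 3, 3, 4
  )
}

#' Generate a synthetic shot campaign
#'
#' One [generate_shot()] per entry of `groups`, with the spectrum
#' normalization scaled by the group's foam areal density (denser/thicker
#' foams couple more laser energy into the electron beam, so behind-tank
#' doses trend upward with areal density) and a ~20% log-normal
#' shot-to-shot jitter. Seeds derive from `global_seed` by the
#' counter-based splitting scheme, so generation is order-independent.
#'
#' @param n_shots Number of shots.
#' @param groups Integer vector in 1..5 (recycled to `n_shots`).
#' @param global_seed Integer seed.
#' @param truth Base [electron_spectrum()] (group 2 reference).
#' @param shot_jitter_rel Log-normal shot-to-shot normalization jitter.
#' @inheritParams generate_shot
#' @return List of [generate_shot()] records.
#' @export
generate_campaign <- function(n_shots, groups = rep(1:5, length.out = n_shots),
                              global_seed = 1, truth = default_truth(),
                              geometry = default_beamline(),
                              noise = noise_config(), maps = FALSE,
                              shot_jitter_rel = 0.2, medium = "water",
                              true_yield_uM_Gy = 0.35,
                              control = forward_control()) {
  if (n_shots == 0) return(list())
  groups <- rep(groups, length.out = n_shots)
  if (!all(groups %in% 1:5)) stop("groups must be in 1..5", call. = FALSE)
  tg <- target_groups()
  areal <- tg$density_mg_cm3 * tg$thickness_um      # mg/cm^3 * um
  areal_ref <- areal[2]
  lapply(seq_len(n_shots), function(i) {
    g <- groups[i]
    seed_i <- split_seed(global_seed, i)
    old <- .Random.seed_save()
    set.seed(split_seed(global_seed, 100000L + i))
    jit <- exp(stats::rnorm(1, sd = shot_jitter_rel))
    .Random.seed_restore(old)
    truth_i <- electron_spectrum(truth$n0 * (areal[g] / areal_ref) * jit,
                                 truth$lambda, truth$t1, truth$t2,
                                 truth$alpha0, truth$delta_alpha)
    generate_shot(truth_i, geometry, noise, seed = seed_i,
                  true_yield_uM_Gy = true_yield_uM_Gy, medium = medium,
                  maps = maps, shot_id = sprintf("shot-%03d", i),
                  group = tg[g, ], control = control)
  })
}

#' Simulated oxygen-depletion experiment (doses to traces to fit)
#'
#' The radiochemistry end of the pipeline in isolation: draw per-shot
#' doses uniformly from `dose_range`, convert to true drops at
#' `true_yield_uM_Gy`, pass each through the lagged noisy sensor, and
#' estimate the drops back from the traces. Feed the result to
#' [fit_o2_slope()].
#'
#' @param n_shots Number of shots.
#' @param dose_range_Gy Uniform dose range (Gy).
#' @param true_yield_uM_Gy Generating yield (uM/Gy).
#' @param initial_o2_uM Pre-shot concentration (uM).
#' @param tau_s Sensor lag (s).
#' @param noise_rel Meter noise.
#' @param seed Integer seed.
#' @param medium Medium label.
#' @return Tibble: `shot`, `dose_Gy`, `true_drop_uM`, `drop_uM`, and the
#'   traces as a list column `trace`.
#' @export
simulate_o2_experiment <- function(n_shots = 4, dose_range_Gy = c(10, 50),
                                   true_yield_uM_Gy = 0.35,
                                   initial_o2_uM = 270, tau_s = 3,
                                   noise_rel = 0.08, seed = 1,
                                   medium = "water") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  doses <- stats::runif(n_shots, dose_range_Gy[1], dose_range_Gy[2])
  traces <- lapply(seq_len(n_shots), function(i) {
    sensor_response(o2_drop_from_dose(doses[i], true_yield_uM_Gy, initial_o2_uM),
                    initial_o2_uM = initial_o2_uM, tau_s = tau_s,
                    noise_rel = noise_rel, seed = split_seed(seed, i),
                    medium = medium)
  })
  tibble::tibble(
    shot = seq_len(n_shots), dose_Gy = doses,
    true_drop_uM = o2_drop_from_dose(doses, true_yield_uM_Gy, initial_o2_uM),
    drop_uM = vapply(traces, function(tr) as.numeric(estimate_drop(tr)),
                     numeric(1)),
    trace = traces)
}

#' Write a shot record to plain-text files
#'
#' Dose maps, region table, oxygen trace and a JSON metadata file, in the
#' same formats the analysis readers consume.
#'
#' @param shot A [generate_shot()] record.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_shot <- function(shot, dir) {
  stopifnot(inherits(shot, "shot_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pl in names(shot$dose_maps)) {
    write_dose_map(shot$dose_maps[[pl]],
                   file.path(dir, sprintf("dose_map_%s.txt", pl)))
  }
  write_regions(shot$region_doses, file.path(dir, "region_doses.csv"))
  write_o2_trace(shot$o2_trace, file.path(dir, "o2_trace.csv"))
  meta <- list(shot_id = shot$shot_id, seed = shot$seed,
               medium = shot$medium,
               tank_dose_true_Gy = shot$tank_dose_true_Gy,
               true_yield_uM_Gy = shot$true_yield_uM_Gy,
               backgrounds = shot$backgrounds,
               truth = unclass(shot$truth))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
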