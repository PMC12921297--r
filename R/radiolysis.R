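#' Escape G-values for the oxygen-consuming channels
#'
#' Radiation-chemical escape yields (species per 100 eV surviving
#' intra-track recombination) of the two species that scavenge dissolved
#' molecular oxygen in irradiated water: hydrated electrons
#' (e_aq- + O2 -> O2-) and hydrogen atoms (H + O2 -> HO2). The defaults
#' are the standard low-LET escape yields G(e_aq-) = 2.65 and
#' G(H) = 0.55; both are parameters, not hard truths.
#'
#' @param g_eaq Escape yield of hydrated electrons (per 100 eV), in \[0, 10\].
#' @param g_h Escape yield of H atoms (per 100 eV), in \[0, 10\].
#' @return An object of class `g_value_set`.
#' @export
g_value_set <- function(g_eaq = 2.65, g_h = 0.55) {
  if (g_eaq < 0 || g_h < 0) stop("G-values must be >= 0", call. = FALSE)
  if (g_eaq > 10 || g_h > 10) stop("G-values above 10/100 eV fail the sanity bound", call. = FALSE)
  structure(list(g_eaq = g_eaq, g_h = g_h), class = "g_value_set")
}

#' Molecular-oxygen consumption yield from G-values
#'
#' Homogeneous-chemistry surrogate: every escaped hydrated electron and H
#' atom consumes one O2, so the oxygen consumption yield is
#' `0.10364 * (G_eaq + G_H)` uM/Gy (one species per 100 eV equals
#' 1.0364e-7 mol/J; 1 Gy = 1 J/kg = 1 J/L in water). With the default
#' escape yields this evaluates to ~0.33 uM/Gy.
#'
#' @param g A [g_value_set()].
#' @return Yield (uM/Gy).
#' @export
#' @examples
#' o2_yield_from_g() # ~0.332
o2_yield_from_g <- function(g = g_value_set()) {
  stopifnot(inherits(g, "g_value_set"))
  uM_per_Gy_per_G() * (g$g_eaq + g$g_h)
}

#' Oxygen drop from dose
#'
#' Linear consumption clamped at full depletion:
#' `drop = min(yield * dose, initial_o2)`.
#'
#' @param dose_Gy Absorbed dose (Gy), >= 0; vectorized.
#' @param yield_uM_Gy Consumption yield (uM/Gy), >= 0.
#' @param initial_o2_uM Initial dissolved-oxygen concentration (uM).
#' @return Concentration drop (uM).
#' @export
o2_drop_from_dose <- function(dose_Gy, yield_uM_Gy, initial_o2_uM = 270) {
  if (any(dose_Gy < 0) || yield_uM_Gy < 0) {
    stop("dose and yield must be >= 0", call. = FALSE)
  }
  pmin(yield_uM_Gy * dose_Gy, initial_o2_uM)
}

#' Oxygen-meter time series
#'
#' @param time_s Sample times (s), non-decreasing.
#' @param o2_uM Concentrations (uM), >= 0.
#' @param shot_time_s Time of the laser shot (s).
#' @param medium Medium label (`water`, `PBS`, `HamF12`, `lysate`).
#' @return A tibble of class `o2_trace` with columns `time_s`, `o2_uM`
#'   and attributes `shot_time_s`, `medium`.
#' @export
o2_trace <- function(time_s, o2_uM, shot_time_s, medium = "water") {
  if (is.unsorted(time_s)) stop("`time_s` must be non-decreasing", call. = FALSE)
  if (any(o2_uM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (sum(time_s < shot_time_s) < 5 || sum(time_s > shot_time_s) < 5) {
    stop("need at least 5 pre-shot and 5 post-shot samples", call. = FALSE)
  }
  out <- tibble::tibble(time_s = time_s, o2_uM = o2_uM)
  attr(out, "shot_time_s") <- shot_time_s
  attr(out, "medium") <- medium
  class(out) <- c("o2_trace", class(out))
  out
}

#' Simulated luminescence-sensor response to a step oxygen drop
#'
#' The true concentration drops by `true_drop_uM` at the shot within a
#' picosecond, but the optical sensor reads it through a first-order lag
#' (oxygen must diffuse from the water into the sensor's polymer layer):
#' `c(t) = c_final + (c0 - c_final) exp(-(t - t0)/tau)`, sampled at the
#' meter cadence. Meter noise is multiplicative Gaussian on the
#' instantaneous depletion signal `c0 - c(t)` — the fluctuations that
#' accompany the drop — so that the relative error of an estimated drop
#' matches `noise_rel` to within window-averaging factors.
#'
#' @param true_drop_uM Step drop (uM).
#' @param initial_o2_uM Pre-shot concentration (uM).
#' @param tau_s Diffusion lag time constant (s), > 0.
#' @param duration_s Trace length (s).
#' @param sampling_s Meter cadence (s), > 0.
#' @param noise_rel Relative meter noise on the depletion signal.
#' @param shot_time_s Shot time (s).
#' @param seed Optional integer seed for reproducible noise.
#' @param medium Medium label.
#' @return An [o2_trace()].
#' @export
sensor_response <- function(true_drop_uM, initial_o2_uM = 270, tau_s = 3,
                            duration_s = 60, sampling_s = 1, noise_rel = 0.08,
                            shot_time_s = 20, seed = NULL, medium = "water") {
  if (tau_s <= 0) stop("`tau_s` must be positive", call. = FALSE)
  if (sampling_s <= 0) stop("`sampling_s` must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  t <- seq(0, duration_s, by = sampling_s)
  depl <- ifelse(t < shot_time_s, 0,
                 true_drop_uM * (1 - exp(-(t - shot_time_s) / tau_s)))
  if (noise_rel > 0) {
    depl <- depl * (1 + stats::rnorm(length(t), sd = noise_rel))
  }
  o2_trace(t, pmax(initial_o2_uM - depl, 0), shot_time_s, medium)
}

# save/restore the RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Estimate the oxygen drop from a trace
#'
#' Difference between the mean over a pre-shot window and the mean over a
#' post-equilibration window (robust to meter fluctuations; no model
#' fit). Negative estimates are clamped to zero and flagged.
#'
#' @param trace An [o2_trace()].
#' @param pre_window_s Length of the pre-shot window ending at the shot (s).
#' @param post_start_s Start of the post window after the shot (s); the
#'   default 20 s is far beyond the few-second sensor lag.
#' @param post_window_s Length of the post window (s).
#' @return Drop (uM) with attribute `clamped` (logical).
#' @export
estimate_drop <- function(trace, pre_window_s = 10, post_start_s = 20,
                          post_window_s = 10) {
  stopifnot(inherits(trace, "o2_trace"))
  t0 <- attr(trace, "shot_time_s")
  pre <- trace$o2_uM[trace$time_s >= t0 - pre_window_s & trace$time_s < t0]
  post <- trace$o2_uM[trace$time_s >= t0 + post_start_s &
                        trace$time_s <= t0 + post_start_s + post_window_s]
  if (!length(pre) || !length(post)) {
    stop("drop-estimation windows contain no samples", call. = FALSE)
  }
  drop <- mean(pre) - mean(post)
  clamped <- drop < 0
  if (clamped) {
    warning("negative drop estimate clamped to 0", call. = FALSE)
    drop <- 0
  }
  structure(drop, clamped = clamped)
}

#' Origin-constrained oxygen-yield fit
#'
#' Least-squares fit of concentration drop against dose with the line
#' constrained through the origin (zero dose consumes no oxygen):
#' `slope = sum(d * drop) / sum(d^2)`. The standard error comes from the
#' residual variance with n - 1 degrees of freedom.
#'
#' @param data Data frame with columns `dose_Gy` (> 0) and `drop_uM`.
#' @param medium Medium label carried into the fit.
#' @return An object of class `yield_fit` with fields `slope_uM_Gy`,
#'   `stderr_uM_Gy`, `n_shots`, `medium`, `data`.
#' @export
#' @examples
#' fit_o2_slope(tibble::tibble(dose_Gy = c(10, 20, 40),
#'                             drop_uM = c(3.5, 7, 14)))
fit_o2_slope <- function(data, medium = "water") {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("dose_Gy", "drop_uM") %in% names(data)))
  if (!nrow(data)) stop("need at least one point", call. = FALSE)
  if (any(!is.finite(data$dose_Gy)) || any(!is.finite(data$drop_uM))) {
    stop("non-finite input", call. = FALSE)
  }
  if (all(data$dose_Gy == 0)) stop("all doses are zero", call. = FALSE)
  if (any(data$dose_Gy <= 0)) stop("doses must be positive", call. = FALSE)
  d <- data$dose_Gy; y <- data$drop_uM
  slope <- sum(d * y) / sum(d^2)
  n <- length(d)
  if (slope < 0) {
    warning("negative fitted yield clamped to 0", call. = FALSE)
    slope <- 0
  }
  se <- if (n >= 2) {
    s2 <- sum((y - slope * d)^2) / (n - 1)
    sqrt(s2 / sum(d^2))
  } else NA_real_
  structure(list(slope_uM_Gy = slope, stderr_uM_Gy = se, n_shots = n,
                 medium = medium, data = data),
            class = "yield_fit")
}

#' @export
print.yield_fit <- function(x, ...) {
  cat(sprintf("<yield_fit> %s: %.3f +/- %s uM/Gy (%d shots, origin-constrained)\n",
              x$medium, x$slope_uM_Gy,
              if (is.na(x$stderr_uM_Gy)) "NA" else sprintf("%.3f", x$stderr_uM_Gy),
              x$n_shots))
  invisible(x)
}

#' Write / read oxygen traces as CSV
#'
#' Columns `time_s,o2_uM` with `#` header comments carrying
#' `shot_time_s` and `medium`.
#'
#' @param trace An [o2_trace()].
#' @param path File path.
#' @export
write_o2_trace <- function(trace, path) {
  stopifnot(inherits(trace, "o2_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# shot_time_s=%.10g", attr(trace, "shot_time_s")),
               sprintf("# medium=%s", attr(trace, "medium")),
               "time_s,o2_uM"), con)
  writeLines(sprintf("%.10g,%.10g", trace$time_s, trace$o2_uM), con)
  invisible(path)
}

#' @rdname write_o2_trace
#' @export
read_o2_trace <- function(path) {
  lines <- readLines(path)
  get <- function(key, default = NULL) {
    i <- grep(paste0("^#\\s*", key, "="), lines)
    if (!length(i)) return(default)
    sub(paste0("^#\\s*", key, "=\\s*"), "", lines[i[1]])
  }
  t0 <- as.numeric(get("shot_time_s"))
  if (is.na(t0)) stop("missing shot_time_s header in ", path, call. = FALSE)
  df <- utils::read.csv(text = lines, comment.char = "#")
  o2_trace(df$time_s, df$o2_uM, t0, get("medium", "water"))
}
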