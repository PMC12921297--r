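# shared fixtures: cheap quadrature settings and toy tables

# constant stopping power S = 2 MeV cm^2/g -> closed-form ranges
const_sp_table <- function(s = 2) {
  e <- exp(seq(log(0.01), log(200), length.out = 25))
  stopping_power_table(e, rep(s, length(e)), material = "const")
}

# coarse-but-adequate forward settings for fitting tests
fast_control <- function() {
  forward_control(n_energy = 80, sample_spacing_mm = 2.5)
}

ref_model <- function() electron_spectrum(7e11, 0.35, 7, 14, 0, 13)

# geometry without magnets: single water-equivalent slab, one plane
slab_geometry <- function(thickness_mm = 10, density = 1,
                          plane_mm = 100, table = default_stopping_power()) {
  beamline_geometry(
    layers = tibble::tibble(name = "slab", position_mm = 20,
                            thickness_mm = thickness_mm,
                            density_g_cm3 = density),
    planes = tibble::tibble(label = "P1", position_mm = plane_mm),
    sp_table = table
  )
}
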