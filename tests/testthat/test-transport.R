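test_that("stopping-power interpolation is exact at nodes and monotone between", {
  tab <- default_stopping_power()
  expect_equal(stopping_power(tab, tab$energies_MeV), tab$total_sp)

  # midpoint query lies between neighboring nodal values
  for (i in c(3, 10, 20)) {
    mid <- sqrt(tab$energies_MeV[i] * tab$energies_MeV[i + 1])
    v <- stopping_power(tab, mid)
    expect_gte(v, min(tab$total_sp[i:(i + 1)]))
    expect_lte(v, max(tab$total_sp[i:(i + 1)]))
  }
  expect_error(stopping_power(tab, 1e4), "range")
  expect_error(stopping_power(tab, 1e-4), "range")
})

test_that("independent water and mylar tabulations agree within 2%", {
  w <- default_stopping_power("water")
  m <- default_stopping_power("mylar")
  for (e in c(0.35, 1.3, 6.5, 22, 85)) {   # off-grid for both tables
    expect_equal(stopping_power(w, e), stopping_power(m, e), tolerance = 0.02)
  }
})

test_that("csda range: closed form for constant S and monotone in energy", {
  tab <- const_sp_table(2)
  expect_equal(csda_range(tab, 10), 5, tolerance = 1e-9)
  e <- tab$energies_MeV[tab$energies_MeV >= 0.1]
  expect_true(all(csda_range(tab, e) > csda_range(tab, e / 2)))

  w <- default_stopping_power()
  ew <- w$energies_MeV[w$energies_MeV >= 0.1 & w$energies_MeV <= 100]
  expect_true(all(diff(csda_range(w, ew)) > 0))
})

test_that("csda range matches a brute-force Riemann sum", {
  tab <- default_stopping_power()
  for (e_hi in c(1, 10, 80)) {
    # 1e5-step midpoint Riemann sum over the same log-log interpolant
    e <- seq(tab$e_cutoff_MeV, e_hi, length.out = 1e5 + 1)
    mids <- (e[-1] + e[-length(e)]) / 2
    riemann <- sum(diff(e) / stopping_power(tab, mids)) +
      tab$e_cutoff_MeV / stopping_power(tab, tab$e_cutoff_MeV)
    expect_equal(csda_range(tab, e_hi), riemann, tolerance = 1e-6)
  }
})

test_that("energy degradation: identity, stopping, linear loss, composition", {
  tab <- const_sp_table(2)
  expect_equal(degrade_energy(tab, 10, 0), 10)
  expect_equal(degrade_energy(tab, 10, 1), 8, tolerance = 1e-9)
  expect_equal(degrade_energy(tab, 10, csda_range(tab, 10)), 0)
  expect_equal(degrade_energy(tab, 10, 99), 0)

  w <- default_stopping_power()
  for (e0 in c(2, 12, 60)) {
    a <- stats::runif(1, 0.1, 1); b <- stats::runif(1, 0.1, 1)
    expect_equal(degrade_energy(w, degrade_energy(w, e0, a), b),
                 degrade_energy(w, e0, a + b), tolerance = 1e-9)
  }
})

test_that("magnet deflection follows the hard-edge dipole model", {
  mg <- magnet_block(0.4, 50, 30)
  expect_equal(magnet_deflection(magnet_block(0, 50, 30), c(1, 10, 100), 50),
               c(0, 0, 0))

  # hand-computed gyroradius at 10 MeV, 0.4 T
  p <- sqrt(10^2 + 2 * 10 * 0.51099895)
  r_mm <- p / (299.792458 * 0.4) * 1000
  expect_equal(r_mm, 87.6, tolerance = 1e-3)
  theta <- asin(50 / r_mm)
  expect_equal(magnet_deflection(mg, 10, 40),
               r_mm * (1 - cos(theta)) + 40 * tan(theta))

  # rigidity monotonicity and the swept-out sentinel
  d <- magnet_deflection(mg, c(10, 20, 50, 100), 40)
  expect_true(all(diff(d) < 0))
  expect_identical(magnet_deflection(mg, 0.5, 40), Inf)
})

test_that("deflection agrees with a Runge-Kutta ray-trace oracle", {
  # RK4 integration of the Lorentz force through the hard-edge field,
  # then free drift to the plane
  ray_trace <- function(b_T, l_mm, drift_mm, e_MeV, n = 1e4) {
    m_e <- 0.51099895
    gamma <- 1 + e_MeV / m_e
    beta <- sqrt(1 - 1 / gamma^2)
    v <- beta * 2.99792458e8
    omega <- 1.602176634e-19 * b_T / (gamma * 9.1093837015e-31)  # cyclotron
    # state (x, s, vx, vs); ds/dt along axis; field region 0..l_mm
    h <- (l_mm * 1.2 / 1000) / v / n
    st <- c(0, 0, 0, v)
    deriv <- function(st) {
      inside <- st[2] >= 0 && st[2] < l_mm / 1000
      c(st[3], st[4],
        if (inside) -omega * st[4] else 0,
        if (inside) omega * st[3] else 0)
    }
    while (st[2] < l_mm / 1000) {
      k1 <- deriv(st); k2 <- deriv(st + h / 2 * k1)
      k3 <- deriv(st + h / 2 * k2); k4 <- deriv(st + h * k3)
      st <- st + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    (abs(st[1]) + drift_mm / 1000 * abs(st[3] / st[4])) * 1000
  }
  mg <- magnet_block(0.4, 30, 30)   # keep r > L for all test energies
  for (e in c(5, 10, 30)) {
    expect_equal(magnet_deflection(mg, e, 40), ray_trace(0.4, 30, 40, e),
                 tolerance = 5e-3)
  }
})

test_that("spectrometer dispersion inverts the deflection map", {
  sp <- magnet_block(0.99, 4, 0)
  for (e in c(1, 5, 10, 50)) {
    x <- magnet_deflection(sp, e, 100)
    expect_equal(spectrometer_dispersion(x, sp, 100), e, tolerance = 1e-6)
  }

  # monotone decreasing energy across the plate
  pos <- seq(2, 60, by = 2)
  expect_true(all(diff(spectrometer_dispersion(pos, sp, 100)) < 0))

  # bisection oracle at plate midpoints
  bisect <- function(x) {
    lo <- 0.5; hi <- 900
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (magnet_deflection(sp, mid, 100) > x) lo <- mid else hi <- mid
    }
    mid
  }
  for (x in c(5, 17, 42)) {
    expect_equal(spectrometer_dispersion(x, sp, 100), bisect(x),
                 tolerance = 1e-5)
  }
  expect_error(spectrometer_dispersion(1e5, sp, 100), "invertible")
})

test_that("forward dose is linear in n0 and vanishes for a null beam", {
  g <- default_beamline()
  reg <- region_spec("area-2", 0, 0)
  m1 <- ref_model()
  m2 <- electron_spectrum(2 * m1$n0, m1$lambda, m1$t1, m1$t2, m1$alpha0,
                          m1$delta_alpha)
  d1 <- forward_dose(m1, g, "RCF2", reg, fast_control())
  expect_gt(d1, 0)
  expect_equal(forward_dose(m2, g, "RCF2", reg, fast_control()), 2 * d1,
               tolerance = 1e-12)

  tiny <- electron_spectrum(1e-30, 0.5, 7, 14, 0, 13)
  expect_lt(forward_dose(tiny, g, "RCF2", reg, fast_control()), 1e-30)
})

test_that("forward dose is additive over disjoint energy bands", {
  g <- default_beamline()
  reg <- region_spec("area-2", 0, 0)
  m <- ref_model()
  full <- forward_control(n_energy = 301, e_min_MeV = 0.15, e_max_MeV = 150)
  # split the band at a shared node so the quadratures tile exactly
  e_nodes <- exp(seq(log(0.15), log(150), length.out = 301))
  k <- 151
  lo <- forward_control(n_energy = k, e_min_MeV = 0.15, e_max_MeV = e_nodes[k])
  hi <- forward_control(n_energy = 301 - k + 1, e_min_MeV = e_nodes[k],
                        e_max_MeV = 150)
  expect_equal(forward_dose(m, g, "RCF2", reg, full),
               forward_dose(m, g, "RCF2", reg, lo) +
                 forward_dose(m, g, "RCF2", reg, hi),
               tolerance = 1e-10)
})

test_that("pencil-beam limit matches the fluence x stopping-power closed form", {
  # nearly monoenergetic spectrum, no magnet, single thin slab: the dose
  # at a small on-axis region is fluence/z^2 * S(E_at_plane) * 1.602e-10
  tab <- default_stopping_power()
  g <- slab_geometry(thickness_mm = 5, plane_mm = 100, table = tab)
  e0 <- 20
  # delta-like band around e0: half-width 0.5% with flat-ish weight
  ctrl <- forward_control(n_energy = 50, e_min_MeV = e0 * 0.995,
                          e_max_MeV = e0 * 1.005, sample_spacing_mm = 0.5)
  m <- electron_spectrum(1e10, 1, 1e6, 1e6, 0, 1e3)  # flat in E and angle
  reg <- region_spec("c", 0, 0, 1, 1)
  got <- forward_dose(m, g, "P1", reg, ctrl)
  n_band <- 1e10 * (e0 * 0.01)              # fluence per sr across the band
  e_at <- degrade_energy(tab, e0, 0.5)
  want <- n_band / 10^2 * stopping_power(tab, e_at) * 1.602176634e-10
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("dose degrades across the tank: RCF2 below RCF1, tank in between", {
  g <- default_beamline()
  m <- ref_model()
  ctrl <- fast_control()
  box <- region_spec("blue-box", 0, 0)
  d1 <- forward_dose(m, g, "RCF1", box, ctrl)
  d2 <- forward_dose(m, g, "RCF2", box, ctrl)
  tk <- tank_mean_dose(m, g, ctrl)
  expect_lt(d2, d1)
  expect_gt(tk, d2); expect_lt(tk, d1)
})

test_that("tank mean dose is n0-linear and stable under grid refinement", {
  g <- default_beamline()
  m <- ref_model()
  coarse <- forward_control(n_energy = 120, tank_axial_n = 5, tank_spacing_mm = 2.5)
  fine <- forward_control(n_energy = 240, tank_axial_n = 10, tank_spacing_mm = 1.25)
  t_c <- tank_mean_dose(m, g, coarse)
  t_f <- tank_mean_dose(m, g, fine)
  expect_equal(t_c, t_f, tolerance = 0.01)

  m2 <- electron_spectrum(3 * m$n0, m$lambda, m$t1, m$t2, m$alpha0, m$delta_alpha)
  expect_equal(tank_mean_dose(m2, g, coarse), 3 * t_c, tolerance = 1e-12)
})

test_that("slab transport conserves energy: deposited + exiting = injected", {
  g <- default_beamline()
  audit <- transport_energy_audit(ref_model(), g, control = fast_control())
  injected <- attr(audit, "injected_MeV")
  balance <- sum(audit$deposited_MeV) + attr(audit, "exiting_MeV")
  expect_equal(balance, injected, tolerance = 1e-9)
  expect_true(all(audit$deposited_MeV >= 0))

  # thick absorber stops everything: exiting ~ 0, deposited ~ injected
  g2 <- slab_geometry(thickness_mm = 500, plane_mm = 600)
  a2 <- transport_energy_audit(ref_model(), g2, control = fast_control())
  expect_lt(attr(a2, "exiting_MeV") / attr(a2, "injected_MeV"), 1e-12)
  expect_equal(sum(a2$deposited_MeV), attr(a2, "injected_MeV"),
               tolerance = 1e-9)
})

test_that("geometry validation and YAML round trip", {
  g <- default_beamline()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_geometry(g, path)
  g2 <- read_geometry(path)
  expect_equal(g2$layers, g$layers)
  expect_equal(g2$planes, g$planes)
  expect_equal(g2$magnet, g$magnet)
  expect_equal(g2$tank, g$tank)

  expect_error(beamline_geometry(
    tibble::tibble(name = c("a", "b"), position_mm = c(10, 5),
                   thickness_mm = 1, density_g_cm3 = 1),
    tibble::tibble(label = "P", position_mm = 50)), "increasing")
  expect_error(beamline_geometry(
    tibble::tibble(name = "a", position_mm = 10, thickness_mm = 5,
                   density_g_cm3 = 1),
    tibble::tibble(label = "P", position_mm = 12)), "inside")
})
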