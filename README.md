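# flashrecon

Dose reconstruction and oxygen-depletion analysis for laser-driven
ultra-high dose-rate (FLASH) electron beams.

Picosecond laser pulses focused into near-critical-density polymer foams
drive direct laser acceleration (DLA) of electrons, producing MeV-range
beams that deposit tens of Gy in a water sample within ~1 ps — dose rates
around 10^13–10^14 Gy/s. At these rates the radiolytic consumption of
dissolved molecular oxygen becomes measurable on a per-shot basis, which
makes such beams a benchmark source for track-structure radiation
chemistry and for FLASH radiotherapy physics. The catch: the dose inside
the sealed water tank cannot be measured directly. It has to be
*reconstructed* from radiochromic films (RCFs) placed along the beam
path, by inverting a forward transport model of the beamline.

`flashrecon` implements that full analysis chain for R users:

- **Beam model.** The DLA electron spectrum is a two-temperature
  exponential with a Gaussian angular profile,

  f(E, α) = N₀ [λ e^(−E/T₁) + (1−λ) e^(−E/T₂)] · e^(−((α−α₀)/Δα)²),

  with N₀ in MeV⁻¹ sr⁻¹, effective temperatures T₁ ≤ T₂ in MeV, and the
  half-angle at half maximum Δα·√(ln 2).
- **Transport.** Deterministic water-equivalent CSDA transport through
  ordered material slabs (ESTAR-style total stopping powers, log-log
  interpolated), with hard-edge dipole magnets for beam cleaning and
  spectrometer dispersion.
- **Film handling.** Plain-text gridded dose maps, named rectangular
  regions, region means and relative deviations, the 5×5 mm "blue box"
  tank projection, two-compartment dose averaging.
- **Reconstruction.** Seeded multi-start Nelder–Mead inversion of the six
  spectrum parameters against six measured film region doses
  (normalization profiled out in closed form), in-tank dose from the
  fitted spectrum, and an X-ray background correction interpolated
  between the front and behind films.
- **Radiochemistry.** G-value surrogate for the oxygen consumption yield
  of the e⁻(aq) + O₂ and H· + O₂ channels (0.10364 µM/Gy per unit total
  G), origin-constrained yield fits of ΔO₂ vs dose, and a first-order-lag
  model of the optical oxygen sensor.
- **Synthetic data.** A generator that emulates complete shots — dose
  maps with smooth log-normal spatial noise, region doses, X-ray
  backgrounds, lagged noisy O₂ traces — so every stage is testable
  without experimental data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for every result type.

## Worked example

Simulate a four-shot oxygen-depletion experiment (doses 10–50 Gy, true
yield 0.35 µM/Gy, 3 s sensor lag, 8% meter noise), estimate per-shot
drops from the traces, and fit the origin-constrained slope:

```r
library(flashrecon)

sim <- simulate_o2_experiment(n_shots = 4, seed = 42)
sim[, 1:4]
#> # A tibble: 4 × 4
#>    shot dose_Gy true_drop_uM drop_uM
#>   <int>   <dbl>        <dbl>   <dbl>
#> 1     1    46.6        16.3    16.5
#> 2     2    47.5        16.6    16.7
#> 3     3    21.4         7.51    7.26
#> 4     4    43.2        15.1    15.2

fit <- fit_o2_slope(sim)
fit
#> <yield_fit> water: 0.352 +/- 0.002 uM/Gy (4 shots, origin-constrained)
```

The fitted slope attributes all dose to electrons. If film backgrounds
show that part of the dose was X-rays (say 4 Gy of a 40 Gy shot), the
slope is re-referenced to the total dose:

```r
xray_corrected_slope(fit$slope_uM_Gy, dose_total_Gy = 40, dose_xray_Gy = 4)
#> # A tibble: 1 × 2
#>   slope_uM_Gy slope_reported_uM_Gy
#>         <dbl>                <dbl>
#> 1       0.317                 0.32

o2_yield_from_g()   # homogeneous-chemistry reference yield, default G-values
#> [1] 0.3316566
```

The corrected slope (~0.32 µM/Gy) lands on the track-structure reference
value (~0.33 µM/Gy) — the agreement the analysis exists to test.

A full dose reconstruction inverts the forward film model:

```r
g  <- default_beamline()
sh <- generate_shot(default_truth(), g, noise_config(), seed = 11, maps = FALSE)
ft <- fit_spectrum(sh$region_doses, g,
                   initial = electron_spectrum(6e11, 0.4, 8, 13, 0, 12),
                   n_starts = 2, seed = 1)
ft
#> <spectrum_fit>
#> <electron_spectrum>
#>   N0 = 4.272e+11 MeV^-1 sr^-1
#>   lambda = 0.087, T1 = 17.3 MeV, T2 = 17.3 MeV
#>   alpha0 = -0.53 deg, delta_alpha = 8.44 deg (HWHM 7.03 deg)
#>   objective (relative) = 0.006325 over 6 regions; converged: TRUE (1282 evals)
#>   in-tank mean dose = 45.26 Gy

sh$tank_dose_true_Gy
#> [1] 44.07325
```

Note what this shows: under 10% film noise the individual spectrum
parameters slide along a well-known degeneracy (bright-soft-wide vs
dim-hard-narrow spectra produce nearly identical film doses), but the
reconstructed *in-tank dose* — the quantity the oxygen analysis needs —
comes back within a few percent of the truth. The methods vignette
(`vignettes/flashrecon-methods.Rmd`) quantifies this.

`run_pipeline(pipeline_config(...))` chains all stages
(simulate → fit → tank dose → yield → X-ray correction) into a
machine-readable JSON report.

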