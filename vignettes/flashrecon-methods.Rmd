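---
title: "Methods: dose reconstruction and oxygen-depletion analysis for laser-driven FLASH electron beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose reconstruction and oxygen-depletion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashrecon)
```

# The measurement problem

A picosecond, ~10^19 W/cm² laser pulse focused into a pre-ionized
near-critical-density polymer foam drives direct laser acceleration
(DLA) of electrons. The resulting beam — tens of nC of MeV electrons in
~1 ps — irradiates a sealed, fully oxygenated water tank. An optical
oxygen sensor on the tank wall records the dissolved-O₂ concentration
before and after each shot; radiochromic films (RCFs) placed along the
beam path record 2D dose distributions outside the tank. The scientific
quantity of interest is the oxygen consumption *yield* (µM of O₂
consumed per Gy of absorbed dose), which benchmarks track-structure
radiation chemistry codes in the homogeneous-chemistry limit.

The dose inside the sealed tank is not directly measurable. `flashrecon`
reconstructs it by fitting a parametric beam model to the film doses
through a forward transport model, then converts measured O₂ drops into
a yield, correcting for the X-ray background that the films record along
with the electrons.

# The beam model

The DLA electron spectrum is modeled as a two-temperature exponential
with a Gaussian angular profile:

$$ f(E, \alpha) = N_0\left[\lambda e^{-E/T_1} + (1-\lambda)e^{-E/T_2}\right]
   \exp\!\left(-\left(\frac{\alpha-\alpha_0}{\Delta\alpha}\right)^2\right), $$

with six parameters: normalization $N_0$ (MeV⁻¹ sr⁻¹), mixture fraction
$\lambda \in [0,1]$, effective temperatures $T_1 \le T_2$ (MeV), pointing
angle $\alpha_0$ and divergence $\Delta\alpha$ (degrees; the half-angle
at half maximum is $\Delta\alpha\sqrt{\ln 2}$). The $(T_1,\lambda)
\leftrightarrow (T_2, 1-\lambda)$ relabeling leaves the model invariant,
so the constructor canonicalizes $T_1 \le T_2$; the reported optimum of
any fit is therefore unique.

Angles are treated as a 1D polar angle about the laser axis (the
measured angular distributions are near-axially symmetric); all
interfaces use degrees.

# Forward transport

Transport is deterministic continuous-slowing-down (CSDA)
transport along straight rays:

* **Stopping powers.** A ~30-point total (collision + radiative) mass
  stopping-power table for water, log-log interpolated, spanning
  0.01–150 MeV. Water, RCF, PEEK and Mylar have stopping powers equal
  within ~2%, which is precisely what justifies treating the whole
  beamline as water-equivalent; a second, independently transcribed
  Mylar table ships for cross-checking the interpolation. Below the
  10 keV cutoff the residual range is taken as $E_{cut}/S(E_{cut})$ and
  electrons are deposited locally.
* **Slabs.** Each layer contributes its areal density (thickness ×
  density); energy at depth is obtained by inverting the precomputed
  cumulative range function, which makes slab traversal exactly
  compositional (a+b ≡ a then b) and energy accounting exactly
  telescoping (deposited + exiting = injected).
* **Magnets.** Hard-edge dipoles: gyroradius $r = p/(299.79\,B)$, bend
  angle $\theta = \arcsin(L/r)$, displacement = in-field sagitta +
  drift·tan θ. Electrons with $r \le L$ are swept out (sentinel `Inf`,
  not an error). The spectrometer energy–position map is the numerical
  inverse of the same model. No multiple scattering and no bremsstrahlung
  buildup are modeled; the synthetic maps approximate scattering realism
  with a smooth multiplicative noise field instead.
* **Dose.** At a detector plane, the differential fluence landing at a
  point (after magnet displacement of each energy) is converted to dose
  via the local stopping power: $D = 1.602\times10^{-10}\,\Phi\,S(E)$ Gy
  with $\Phi$ in cm⁻². Region doses are averages over a sampling lattice
  anchored at multiples of the lattice spacing, which makes them exactly
  consistent with pixel-center region means of the generated dose maps.

Default quadrature: 160 log-spaced energy nodes (0.15–150 MeV), trapezoid
rule. The tank dose averages 7 axial slices × a 2 mm transverse lattice
over the central 5×5 mm sensor-relevant column. Fits and large test
campaigns use a coarser but verified-converged setting (80 nodes, 2.5 mm
sampling); the test suite checks that halving the grid changes the tank
dose by < 1–2%.

## Default beamline geometry

The packaged geometry reproduces the irradiation setup: protective layer
(150 µm Al + three RCFs) at 20 mm from the target, a 0.4 T cleaning
magnet at 30 mm, RCF#1 at 50 mm, 2 mm PEEK walls around 30 mm of water,
RCF#2 directly behind the tank, and RCF#3 at 125 mm behind a second
0.4 T dispersive magnet (that second magnet is what makes RCF#3 an
energy-dispersed plane). Exact axial positions, region centers, and
magnet effective lengths are not published; the packaged values are
explicit assumptions. Two of them deserve comment:

* The cleaning magnet's effective length is 10 mm. A much longer 0.4 T
  hard-edge field would deflect the entire sub-50 MeV beam tens of mm
  off-axis, leaving the on-axis tank essentially unirradiated —
  inconsistent with the tens of Gy per shot the tank demonstrably
  receives and with the few-mm lateral displacement visible on the
  films. 10 mm reproduces both.
* The six reconstruction regions (three per film behind the tank) are
  placed to straddle the beam axis and the deflection side, sampling
  both the angular wing and the energy-dispersed flank.

# The inverse problem

`fit_spectrum()` minimizes the sum of squared *relative* residuals
between measured and modeled region doses (doses span tens of Gy across
regions, so absolute residuals would let one bright region dominate).
The normalization $N_0$ enters linearly, so it is profiled out in closed
form at every objective evaluation; the remaining ≤5 shape parameters
are optimized by Nelder–Mead on logit-transformed coordinates (which
enforces the box bounds exactly while staying derivative-free), with
seeded multi-starts jittered ~20% around the initial point and a final
polish from the best optimum. An `objective = "absolute"` variant is
provided; with all shape parameters frozen its profiled scale is the
classic linear least-squares solution, which the tests verify against
the optimizer.

With six data points and six parameters, identifiability is marginal by
construction. Two guards are built in:

* $\alpha_0$ is frozen at 0° unless the left/right asymmetry of the
  measured doses exceeds 10%.
* The default bounds encode what the reference-shot diagnostics
  establish about this beam class ($T_1 \in [3,20]$, $T_2 \in [8,30]$
  MeV, $\Delta\alpha \in [5,25]$°, $N_0 \in [10^9, 10^{14}]$).

## What the fit can and cannot recover

On noiseless forward-generated doses the fit closes the loop: objective
below 10⁻⁶ and parameters recovered from a ~10% perturbed start (the
suite asserts $T_1, T_2$ within 5%, $\lambda$ within 0.1).

Under realistic 10% film noise the picture changes, and it is a property
of the *measurement design*, not of the optimizer: a singular-value
analysis of the log-dose Jacobian shows that for any placement of six
5×5 mm regions on the two behind-tank films, the
($N_0, T_2, \Delta\alpha$) sector retains a direction with sensitivity
~0.2–0.3, i.e. a "brighter but softer and wider" spectrum is nearly
indistinguishable from a "dimmer, harder, narrower" one. Ten-percent
noise therefore moves the individual parameters by tens of percent no
matter how the fit is run. The quantity the method exists for — the
volume-averaged in-tank dose — interpolates the same observable the fit
matches and is robust: across noisy synthetic campaigns the median
reconstructed tank-dose error is ~10–13% (asserted < 15% in the suite),
with ≥ 90% of fits converging. Users should treat the fitted spectrum
parameters as an effective parameterization of the dose field, not as a
spectrometer measurement.

## X-ray background

The films record keV X-rays along with electrons (~10 Gy on the front
film, ~1 Gy behind the tank for a representative shot). The in-tank
X-ray dose is interpolated log-linearly in water-equivalent areal depth
between the two films, evaluated at the tank's axial midpoint — for the
default geometry that abscissa is ≈ 0.5, giving ≈ √(front·behind). The
electron-only yield slope $s$ is then re-referenced to the total dose:
$s_{corr} = s\,(D_{tot} - D_x)/D_{tot}$, a linear contraction. Reported
slopes are rounded to two decimals, half away from zero.

# Radiochemistry

In oxygenated water the escaped (post-track) reducing species consume
dissolved O₂ via e⁻(aq) + O₂ → O₂⁻ and H· + O₂ → HO₂. In the
homogeneous-chemistry limit each escaped species removes one O₂, so the
yield is

$$ Y = 0.10364\,(G_{e^-_{aq}} + G_{H}) \;\mu M/Gy, $$

since one species per 100 eV equals $1/(100\,e\,N_A)$ mol/J and 1 Gy
deposits 1 J per liter of water. The package defaults
$G_{e^-_{aq}} = 2.65$, $G_H = 0.55$ per 100 eV are the standard low-LET
escape yields; they give $Y = 0.33$ µM/Gy, matching the track-structure
reference value for 1 MeV electrons in sealed oxygenated water. Both
G-values are configuration, not hard-coded truths. No inter-track
recombination or dose-rate dependence is modeled: in the 0–50 Gy regime
the consumption is treated as strictly proportional to dose, which also
means the drop computed from a mean dose equals the mean of pixelwise
drops — the identity that licenses working with volume-averaged doses.

## Sensor model

The physical O₂ drop is complete within ~1 ps, but the meter samples at
1 s cadence and reads the near-surface layer of the sample through a
polymer sensor foil, so the recorded drop develops over several seconds.
This is modeled as a first-order lag with τ = 3 s (default; the few
seconds of diffusion equilibration observed experimentally). Meter noise
is multiplicative Gaussian on the instantaneous depletion signal
$c_0 - c(t)$ — the fluctuations that accompany the drop — with default
amplitude 8%, chosen so the relative error of an estimated drop matches
the 7–10% per-point error the measurement exhibits. Noise proportional
to the absolute ~270 µM concentration would bury a 3–17 µM drop entirely
and is not what the recorded traces show. Drops are estimated by window
means (10 s pre-shot vs 10 s starting 20 s post-shot), which is robust
to fluctuations without assuming the lag model is exact; negative
estimates are clamped to zero and flagged.

## Yield fitting

ΔO₂ vs dose is fitted by origin-constrained least squares
($(0,0)$ fixed on physical grounds): slope = Σdᵢyᵢ/Σdᵢ², standard error
from residual variance with n−1 degrees of freedom. Fits are unweighted;
per-medium slopes are labels (water vs culture medium), with no
mechanistic medium model.

# Synthetic data

`generate_shot()` emulates the statistical structure of the real data:

* forward-model dose maps (0.25 mm pixels, flatbed-scan class) times a
  smooth multiplicative log-normal field (Gaussian-filtered white noise,
  2 mm correlation length, mean-corrected), amplitude 10% behind the
  tank and 25% in front — landing region relative deviations in the
  observed 5–20% and 10–40% bands;
* uniform X-ray backgrounds (10 Gy front / 1 Gy behind by default);
* region doses computed from the maps (exactly consistent by shared
  lattice), or drawn directly as forward dose × log-normal factors when
  maps are skipped for speed;
* the O₂ trace driven by the true tank dose × the configured yield
  (0.35 µM/Gy default) through the lagged noisy sensor;
* per-shot in-tank doses landing in the experimental 20–50 Gy range at
  the default truth spectrum ($N_0 = 7\times10^{11}$, λ = 0.35,
  $T_1 = 7$, $T_2 = 14$ MeV, Δα = 13°).

Campaign generation scales $N_0$ with the target group's foam areal
density (plus 20% log-normal shot-to-shot jitter), reproducing the
observed upward dose trend with areal density. Seeds derive from the
global seed by a fixed multiplicative-hash counter scheme, so generation
is order-independent and bit-reproducible.

What the generator does *not* emulate: film LET response and calibration
curves, scanner artifacts, electromagnetic-pulse transients, multiple
scattering (beyond the smooth noise field), and proton dose (protons are
stopped upstream of the tank in the modeled setup). Passing closed-loop
tests therefore demonstrates the self-consistency of the analysis under
the stated noise structure, not the absence of these systematic effects
in real data.

# Numerical choices

* CODATA physical constants to ≥ 6 significant figures.
* Range integral: trapezoid on a ~4000-point log grid merged with the
  table nodes (relative error < 10⁻⁶ against brute-force Riemann sums).
* Energy quadrature: trapezoid on log-spaced nodes; additive over bands
  that share a node, linear in $N_0$ to machine precision.
* Optimizer: Nelder–Mead, `reltol` 10⁻¹², 600 iterations per start, 8
  starts by default (2–4 in the test suite and pipeline, where the
  problems are warm-started); convergence is reported, never silent.
* Degenerate inputs: all-zero measured doses return the lower $N_0$
  bound with `converged = FALSE` and a warning; a zero behind-film
  background with nonzero front falls back to the geometric mean and is
  flagged approximate; region/window selections that contain no
  pixels/samples are errors, not NAs.
* Rounding of reported quantities: half away from zero (integer Gy for
  compartment doses, two decimals for slopes).
* Problem sizes in the shipped tests: 30-shot noisy campaigns, 100
  replicate yield experiments, 80-node quadrature — chosen as the
  smallest sizes at which the asserted statistics are stable.

# Known limitations

* The spectrum parameters are collectively, not individually,
  identified by six behind-tank film doses (see above); only the tank
  dose should be quoted with confidence.
* The water-equivalence assumption (one stopping-power table for all
  materials) is good to ~2% for the materials present but would not hold
  for high-Z components.
* Straight-ray CSDA underestimates lateral spreading for low-energy
  electrons; the packaged geometry keeps detector planes close enough
  that this mainly affects sub-MeV components that do not reach them.
* The X-ray interpolation abscissa (areal-depth log-linear) is a
  documented contract, not a measured attenuation curve.
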