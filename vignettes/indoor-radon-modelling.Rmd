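---
title: "Modelling indoor radon in a naturally ventilated room"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling indoor radon in a naturally ventilated room}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonroom)
```

## The problem

Radon-222 is a radioactive noble gas (half-life 3.8 d) exhaled by soil and
building materials. Indoors it accumulates, and its inhaled progeny are the
second cause of lung cancer after smoking; EU basic safety standards set a
300 Bq m^-3 reference level for dwellings and workplaces. The two levers a
modeller has are the source strength (surface exhalation) and the
ventilation rate, and the two standard descriptions are

* a **well-mixed (box) model** — one ordinary differential equation for the
  room-average activity concentration, and
* a **computational fluid dynamics (CFD) model** — steady incompressible
  airflow plus an advection–diffusion–decay equation for the radon
  concentration field, which resolves *where* in the room radon
  accumulates.

`radonroom` implements both for a single rectangular room (default
3.0 × 4.0 × 2.8 m, 33.6 m^3) with one window acting as a velocity inlet and
one door acting as a pressure outlet, in two scenarios: **open door** (the
whole door is an outlet) and **closed door** (only a thin under-door gap
is). It also implements the dose assessment and the comparison statistics
used to confront predictions with detector readings.

## The models

### Airflow

Steady incompressible continuity and momentum,

$$\nabla\cdot U = 0,\qquad
\rho\,\nabla\cdot(U U) = -\nabla p + \nabla\cdot(\mu_e \nabla U),$$

with effective viscosity $\mu_e = \mu + \mu_t$, are solved with SIMPLE
pressure–velocity coupling on a uniform staggered Cartesian grid. Two
closures are available:

* `constant_nu_eff` (default): a single effective kinematic viscosity,
  molecular plus an inlet-scale turbulent estimate
  $\nu_t = C_\mu^{1/4}\sqrt{k_{in}}\,\ell$ with 5 % inlet intensity and
  $\ell = 0.07 D_h$ ($D_h$ the window hydraulic diameter). At 1 air change
  per hour the inlet speed is only ~0.01 m s^-1 and the window Reynolds
  number is a few hundred, so the flow is at most weakly turbulent and a
  constant effective viscosity is a defensible desk-scale closure.
* `k_epsilon`: the standard k–ε model (Cμ = 0.09, C1 = 1.44, C2 = 1.92,
  σk = 1.0, σε = 1.3) with equilibrium log-law wall functions, blended to
  the laminar stress when the wall cell sits in the viscous sublayer (as it
  does at these speeds).

The inlet velocity follows from the air-change rate,
$V = \mathrm{ACH}\cdot V_{room}/A_{vent}$ (in m h^-1, divided by 3600 for
SI); the solver rescales it so the volumetric inflow through the *snapped*
window patch is exact. Outlets use a zero-gradient profile that is globally
mass-corrected each iteration (the standard "outflow" treatment); with a
single contiguous outlet region this is equivalent to a uniform-pressure
outlet for the quantities of interest, and it makes the global mass balance
exact by construction. Convergence is declared when the relative change of
the velocity field between consecutive iterations falls below the
tolerance (default 1e-6), the same style of criterion as the original
study; scaled residuals are recorded alongside.

Advection is discretized with the hybrid (central/upwind) scheme by
default. Under-relaxation defaults are 0.7 (momentum), 0.3 (pressure),
0.5 (turbulence).

### Radon transport

On the frozen flow field, the steady scalar equation

$$0 = S + \nabla\cdot(D_e\nabla C) - \nabla\cdot(U C) - \lambda C$$

is discretized with conservative first-order upwind fluxes (the resulting
matrix is an M-matrix, so the solution is positivity-preserving) and solved
directly (sparse LU). $D_e = D + \nu_t/Sc_t$ with $D = 1.2\times10^{-5}$
m^2 s^-1, $Sc_t = 0.7$; $\lambda = 2.1\times10^{-6}$ s^-1. Boundary
conditions: the inlet advects the outdoor concentration (10 Bq m^-3) with
no diffusive inlet flux — this makes the strong-mixing limit reduce
*exactly* to the box model, which is a tested invariant; outlets are
advective-outflow; walls carry either the prescribed exhalation flux
(`boundary_flux` mode, the physical default, E = 3.1 Bq m^-2 h^-1 measured
for cement) or zero flux with a uniform volumetric source (`volumetric`
mode, which mirrors the analytical model's structure).

### The two source magnitudes

The published analytical concentrations imply, by inverting the steady box
model, an effective generation rate of about 65 Bq m^-3 h^-1, while
summing the measured exhalation rate over the room surfaces
(`volumetric_generation_rate()`) gives 5.83 Bq m^-3 h^-1 — an
order-of-magnitude gap that the source study does not explain. The package
therefore never picks silently: `calibrate_generation()` exposes the
inversion, both `G` values can be passed explicitly, and the reproduction
of the published CFD volume averages uses the calibrated value, as the
comparison tables themselves do.

### Box model and dose

$$C_{ss} = \frac{G + \lambda_V C_{out}}{\lambda_{Rn} + \lambda_V},\qquad
C(t) = C_0 e^{-\lambda t} + C_{ss}(1 - e^{-\lambda t}),\quad
\lambda = \lambda_{Rn} + \lambda_V.$$

The printed closed form of the source study has no outdoor term, but its
analytical values asymptote to the outdoor concentration at high
ventilation; with the $\lambda_V C_{out}$ supply term the model reproduces
every published analytical entry to two decimals after calibrating G from
a single entry. The literal form is kept behind
`include_outdoor_inflow = FALSE`.

The annual effective dose is $AED = C\,F\,t\,K$ with equilibrium factor
F = 0.4 (UNSCEAR), occupancy t = 2000 h yr^-1 and K = 12 nSv per
Bq h m^-3 (ICRP 115), reported in mSv yr^-1. Published dose values are
printed to two decimals; the exact products differ from them by up to
0.006 mSv, so comparisons use a ±0.01 mSv rounding band.

## Geometry, grids and defaults that required a choice

The source room is described only loosely, so the following were fixed
once as package defaults:

* **Window placement**: centred on the x = Lx wall (1.2 × 0.8 m), i.e. at
  (y, z) = (Ly/2, Lz/2).
* **Door placement**: on the y = 0 wall, 1.0 m wide × 2.2 m tall, left
  edge 0.1 m from the corner (a plausible reveal).
* **Under-door gap**: the boundary-condition table lists the bottom of the
  door as a pressure outlet in *both* scenarios, implying a gap; its size
  is unstated and defaults to 0.03 m.
* **Grid**: uniform Cartesian with patch snapping (at least one face strip
  per patch, so the gap survives coarse grids at the price of an inflated
  snapped area — first-order in the spacing). This replaces the original
  unstructured mesh of ~1.3 million cells; the grid-convergence study is
  reproduced qualitatively with `refine_series()`.
* **Coordinates**: origin at the room corner such that detector point A
  (2.9, 0.1) sits near the x = 3 / y = 0 corner. The detector notes claim
  20 cm wall clearance while the table coordinates say 10 cm; the
  coordinates are taken at face value.
* **Humid air**: ideal-gas mixture of dry air and vapour with a
  Magnus-type saturation correlation; Sutherland viscosity (humidity
  effect on μ neglected). Default 24 °C, RH 50 %, 101325 Pa. Only the
  property model is provided; the humidity–concentration response curve of
  the source study is out of scope.
* The momentum source S is taken as zero (no body forces, isothermal
  flow); the radon source enters only the scalar equation.

## What the synthetic-data module emulates

* `manufactured_case()` builds a divergence-free trigonometric velocity
  field *discretely* (from a streamfunction differenced at cell corners,
  so the staggered divergence vanishes to machine precision), an exact
  concentration field, and the source that makes it a steady solution.
  Refining 16³ → 32³ must reduce the L2 error by at least 1.8×
  (first-order upwind); this verifies the transport discretization.
* `synthetic_measurements()` stands in for the detectors: samples of a
  ground-truth field perturbed by mean-one multiplicative lognormal noise
  (default σ = 10 %, a typical passive-detector uncertainty; the source
  study states no error model) or additive Gaussian noise. All randomness
  flows through the model's seed and the global RNG state is restored.
  With σ = 10 % the mean relative deviation must approach the half-normal
  mean σ√(2/π) ≈ 7.98 %.

What passing these tests does **not** show: real detectors integrate over
weeks, respond to humidity, and sit in flows with thermal stratification
and occupant disturbance, none of which the generator represents.

## Verification and validation suite

* Lid-driven cavity at Re = 100 against the published Ghia, Ghia & Shin
  (1982) centreline profile, within 5 %. The reference is two-dimensional,
  so the preset runs quasi-2D (64 × 1 × 64, free-slip side walls); a true
  3D cavity differs from the 2D reference by more than the band itself.
* Mirror symmetry: a symmetric inlet/outlet configuration must give a
  y-mirror-symmetric field to solver tolerance.
* Global mass balance exact; per-cell continuity below tolerance;
  steady activity balance below 1e-4 relative (it closes to rounding
  because the scheme is conservative and the system is solved directly).
* Strong-mixing limit (diffusivity × 1e6) within 2 % of the box model.
* The volume average decreases strictly over the six-ACH sweep
  {0.3, 0.5, 1, 1.5, 2, 4.3} h^-1 and the floor-adjacent layer
  (z < 0.3 m) exceeds the volume average in boundary-flux mode, matching
  the reported spatial pattern.

Problem sizes: unit tests run the room at 4 cells per metre (15 × 20 × 11)
and the reproduction of the published volume averages at 10 cells per
metre (30 × 40 × 28, 33 600 cells), where a flow solve converges in
roughly 700 SIMPLE iterations and the direct radon solve takes on the
order of a minute. These sizes were chosen as the coarsest grids whose
volume averages sit well inside the comparison band; commercial-code
agreement cell-for-cell is not attainable or claimed at desk scale — the
reproduction criterion is the ±15 % band on the two volume averages.

## Numerical edge cases

* Zero ventilation gives the exact zero flow field and the radon problem
  remains well posed through decay and diffusion.
* Zero sources with zero decay give an exactly uniform field at the
  outdoor concentration. With the physical decay constant the steady
  average sits about λRn/λV below it (0.75 % at 1 ACH) — a real feature
  of the model, not an artefact, and the tests assert it as such.
* Outflow faces are clamped to non-negative outward flow before mass
  scaling, which prevents start-up reverse flow from destabilizing the
  outlet.
* k and ε are floored at 1e-14 / 1e-20; μt is capped at 1e5 μ.
* `calibrate_generation()` refuses observations below the
  outdoor-supported floor λV C_out / (λRn + λV).

## Known limitations

* First-order upwind for the scalar (and hybrid for momentum) is
  diffusive; the original study used second-order discretizations in a
  commercial code. The acceptance band absorbs the difference.
* The k–ε implementation targets robustness at low indoor velocities; it
  is exercised by property tests, not by a turbulent validation case —
  at these Reynolds numbers no strongly turbulent regime exists in the
  room to validate against.
* Radon progeny, thoron, thermal stratification, wind-driven ventilation
  prediction and transient meteorology are out of scope; ACH is an input.
* The RH-dependence of the indoor concentration is not reproduced
  quantitatively; only RH-dependent air properties are provided.

## A worked sweep

```{r, eval = FALSE}
G <- calibrate_generation(221.60, ach = 0.3)   # from the published table
sweep <- run_ach_sweep(list(grid = list(resolution = 4)),
                       ach_list = c(0.3, 0.5, 1, 1.5, 2, 4.3),
                       source_mode = "volumetric", G = G)
sweep
```

The pipeline (`run_pipeline()`) writes VTK fields, the detector-point
probe table, the analytical comparison and the dose summary, plus a JSON
manifest with file checksums; identical configurations reproduce
bit-identical outputs.
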