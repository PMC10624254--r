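---
title: "Methods: voxel-phantom RF dosimetry and thermal simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-phantom RF dosimetry and thermal simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voxdosim)
```

# The problem

Assessing RF exposure of young children in 7 T MRI requires three linked
models: a labeled voxel anatomy, an electromagnetic solve of the transmit
coil loaded with that anatomy, and a thermal model of the resulting tissue
heating. Real pediatric voxel models are built by segmenting MRI/CT data and
validated with multi-rater overlap metrics and literature organ values.
`voxdosim` implements the computational chain on synthetic phantoms —
concentric-shell heads standing in for anatomies that cannot be
redistributed — together with the segmentation validation framework itself.

# Phantom construction

A phantom is a `label_volume`: a 3-D integer grid with spacing (mm), world
origin and a label-to-tissue map; label 0 is exterior air, voxel centers sit
at `origin + index * spacing` (0-based, axis order x, y, z). The generator
`make_layered_head()` bins voxel centers by radius into concentric shells.
Its defaults are the study conditions: a five-layer head (skin to 80 mm,
skull to 79 mm, CSF to 75 mm, grey matter to 71 mm, white-matter core of
67 mm) — the approximate head radius of a preschool child — with a skin
shell of 1.0 mm, the reference skin thickness for this age.

Three assembly rules mirror how real voxel models are finalized:

* **Priority merge** — when hierarchical segmentations overlap, the voxel
  takes the *highest* label (small structures get high labels so they
  survive overlaps). Implemented as a per-voxel max, hence idempotent and
  order-independent.
* **Supplant** — in-body voxels left unlabeled inherit the label of the
  nearest labeled voxel (Euclidean, in mm). Equidistant donors are resolved
  to the *smallest* label: the reference tool's behavior is unspecified, and
  a deterministic tie-break is required for reproducible phantoms.
* **Skin shell** — a 1.0 mm shell cannot be realized by radial binning on a
  grid coarser than 1 mm; the outermost layer is then snapped to a one-voxel
  outward shell and the achieved thickness (= spacing) is recorded in the
  `skin_thickness_achieved` attribute. Inner layers thinner than the
  spacing are rejected outright rather than silently dropped.

Scalar volumes are resampled with a separable Lanczos kernel of order
`a = 3` (the standard choice; only the method, not the order, is prescribed
by the source workflows), with per-sample weight normalization so constants
are preserved exactly and border samples clamp. Label grids always resample
nearest-neighbor — interpolating labels would manufacture non-physical
tissue codes.

`perturb_mask()` emulates inter-rater variability: exact morphological
dilation/erosion (6-connected), or boundary-noise flips of interface voxels
with a given probability, bit-reproducible under a seed. This emulates the
*magnitude* of rater disagreement (fractions of a voxel to a couple of
voxels at the boundary), not its anatomical structure: raters err
systematically at low-contrast interfaces, not uniformly at random, so
passing tests show metric correctness, not realism of simulated raters.

# Tissue properties and age scaling

The packaged table carries, per tissue, the relative permittivity and
electrical conductivity of a 3.5-year-old at 297.2 MHz together with the
adult-to-child conversion ratios (adult value = child value / ratio), the
basal perfusion (ml min^-1 kg^-1) with its ratio, and density, specific
heat, thermal conductivity and metabolic heat rate columns. The last four
carry no age dependency. Dielectric and perfusion scaling is multiplicative:
`scale_properties_to_age()` applies child = adult x ratio.

Decisions worth recording:

* **Liquids.** Blood, CSF, vitreous and aqueous humor, intestine contents,
  urine and bile keep adult dielectric properties at all ages, so their two
  dielectric ratios are pinned to 1 and validated. Their *perfusion* ratios
  are kept exactly as tabulated (CSF 2.21, vitreous humor 0) — the liquid
  rule is a statement about dielectrics, not perfusion.
* **Thermal columns.** Density, heat capacity, conductivity and metabolic
  rate are not part of the published property table; the fixture ships
  documented per-tissue defaults in the style of the standard tissue
  database, and users may override any column.
* **Frequency.** The dielectric columns are tabulated at 297.2 MHz while
  the EM solve is nominally "at 298 MHz" in the source workflow; the table
  stores its own frequency as an attribute and solvers take theirs from
  configuration (default 297.2 MHz). Neither is silently preferred.
* **Units of perfusion.** The bioheat perfusion term as commonly printed
  (W in ml min^-1 kg^-1) is dimensionally inconsistent; the solver uses the
  volumetric Pennes form `rho_b c_b omega (T - T_b)` with
  `omega [1/s] = W * 1e-6 / 60 * rho_tissue`, which restores W m^-3 while
  honoring the tabulated W. `perfusion_to_volumetric()` is that conversion.
* **Blood constants.** rho_b = 1050 kg/m^3, c_b = 3617 J kg^-1 degC^-1,
  T_b = 37 degC are standard reference values, configuration-exposed, and
  not asserted to be the source's (unstated) choices.

# EM exposure

`fdtd_solve()` is a single-frequency Yee FDTD solver (compiled, Rcpp):

* Uniform isotropic grid; materials inherited per cell; semi-implicit
  conductivity update. Time step `cfl * dx / (c sqrt(3))` with
  `cfl = 0.99`, snapped to an integer number of steps per period.
* Sources are impressed currents with a raised-cosine ramp (3 periods by
  default). The birdcage is 16 axial rung currents at
  `theta_n = 2 pi n / 16` carrying phases `-theta_n` (mode 1, circularly
  polarized co-rotating with B1+), surrounded by a one-voxel perfectly
  conducting shield cylinder. Each rung is split bilinearly over the four
  nearest voxel columns: snapping rungs to single columns breaks the
  coil's 16-fold symmetry and leaks a spurious counter-rotating component
  (|B1-|/|B1+| of order 10% at 4-8 mm grids); with bilinear placement the
  empty-coil center is circularly polarized to better than 0.01%.
* A PEC cell mask suppresses an E component when *either* cell sharing its
  staggered edge is PEC. Zeroing only the cells' "own" components biases
  the shield surface by half a cell in +x/+y and measurably distorts the
  polarization; the either-cell rule is mirror-symmetric.
* Outer boundaries per axis: first-order Mur absorbers (default), PEC, or
  PMC. PMC faces use image updates (tangential E symmetric, tangential H
  antisymmetric); combined PEC/PMC side walls turn the solver into a 1-D
  TEM channel, which the plane-wave skin-depth oracle uses.
* Steady state is declared when the period-integrated electric field energy
  changes by less than `tol` (default 1%) between successive periods (after
  at least `min_periods`); phasors are then extracted by discrete Fourier
  projection at the drive frequency over `measure_periods` (default 3)
  further periods, and collocated to cell centers. Multi-period projection
  matters in low-loss domains, where startup ring-down at cavity resonances
  decays slowly and aliases into a single-period projection.
* Phasor convention `e^{+i omega t}`; `|E|` is the peak amplitude, hence
  SAR = `sigma |E|^2 / (2 rho)` with the explicit factor 2 to RMS. SAR is
  defined only on tissue voxels; air contributes neither mass nor power.

Normalization follows the flip-angle argument: a rectangular pulse of
duration tau produces flip angle `theta = gamma B1 tau`, so a 90-degree,
3 ms pulse needs `B1 = 1.957 uT`, rounded to the conventional 2 uT target.
`normalize_fields()` scales all phasors so |B1+| *amplitude* equals the
target at the coil center; the alternative RMS reading of the target would
scale every reported SAR by a factor 2 (RMS amplitude = peak/sqrt(2), SAR
quadratic), and amplitude is chosen as the default because the
normalization pulse argument is itself an amplitude statement.

**10 g mass-averaged SAR.** For each tissue voxel a centered cube grows
until its tissue mass reaches 10 g; the outermost shell is weighted
fractionally so the averaging mass is exact (IEC-style cube averaging in
spirit — the published quantity is named only "10 g mass averaged SAR").
Air is excluded from both mass and average. Voxels whose cube would leave
the grid before reaching 10 g inherit the largest valid neighboring
average, and their count is reported. The implementation uses 3-D
summed-area tables (O(1) cube sums per radius) and is tested against an
exhaustive brute-force cube search.

# Bioheat

`steady_state()` and `transient()` solve the Pennes equation by finite
volumes on tissue voxels only (7-point stencil, harmonic-mean face
conductivity). Air carries no degrees of freedom: a tissue face adjacent to
exterior air gets the Robin condition with `h_ext` (6 W m^-2 degC^-1), a
face adjacent to an internal air cavity gets `h_int`
(10 W m^-2 degC^-1); both reference the 23 degC ambient. Radiative and
evaporative losses are omitted (only convective coefficients are
specified). Thermoregulation uses the impaired model — perfusion stays at
its basal value at every temperature, the conservative choice — with a
pluggable response-curve variant for testing.

The default integrator is backward Euler with a sparse Cholesky
factorization computed once and reused across steps (coefficients are
constant under impaired thermoregulation); it is unconditionally stable
for the 900 s default exposure at 5 s steps. An explicit forward-Euler
scheme is retained for cross-checks and enforces its Gershgorin stability
bound, reporting the bound when rejected. The initial state of an exposure
run is the room-equilibrium steady state (the pre-scan body temperature is
otherwise unspecified).

Oracles: insulated perfused tissue must equilibrate at
`T_b + rho Q / (rho_b c_b omega)`; a uniform insulated block must follow
the lumped exponential with `tau = rho c / (rho_b c_b omega)`; a 1-D rod
with Robin ends has an exact discrete solution by flux telescoping; and a
source-free convective phantom must relax to the room temperature.

# The study runner

`run_exposure_study()` executes phantom -> age-scaled properties -> FDTD ->
B1+ normalization -> SAR -> 10 g SAR -> equilibrium -> 900 s transient ->
report for each configured phantom, then the cross-phantom percent
differences `100 (other - reference) / reference`, rounded to integer
percent for SAR comparisons and 2 decimals for temperatures (the published
comparison precisions). All physical defaults (297.2 MHz, 2 uT, 23 degC,
6/10 W m^-2 degC^-1, 900 s) live in `study_config()`, never in the
pipeline.

**Problem sizes.** The study grid is 4 mm isotropic: the EM domain is
107 x 107 x 81 cells (~0.93 M; shield plus a 6-cell margin), ~440 time
steps per period, and a lossy head converges in 4-8 periods, so one
phantom's EM solve is 3-4 minutes on one CPU and the two-phantom study
about 9 minutes; the thermal stage (~10^5 tissue voxels, 180 implicit
steps) adds seconds. The same pipeline runs at 8 mm in under a minute for
exploration, at the cost of a thicker snapped skin shell and coarser SAR
hot spots.

# Scope of validation

The synthetic spheres reproduce the *chain* — layered dielectrics inside a
realistic coil geometry, surface-dominated SAR, perfusion-limited heating —
but not anatomical field focusing, inter-tissue SAR heterogeneity, or the
absolute values published for real child models, which require the original
anatomies and sub-millimeter commercial solves. Tests therefore anchor on
(a) closed-form and brute-force oracles for every operator and (b) the
published *arithmetic* (score-table statistics, normalization target,
comparison percentages), not on the headline W/kg and degC values.

Known limitations: first-order Mur absorbers (not PML) behind a closed
shield; an impressed-current coil rather than a tuned resonant circuit, so
port voltages and normalization factors of commercial co-simulations have
no counterpart here; no dielectric dispersion (single-frequency
properties); no systemic (core-temperature) thermoregulation feedback; and
population SD as the default in `summarize_scores()` — the published
per-rater Dice SDs follow the population convention while the
Hausdorff SDs follow the sample convention, so no single choice reproduces
all printed SDs; the population default reproduces the Dice set and the
overall values, and `sd_type = "sample"` switches.
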