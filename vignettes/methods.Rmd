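---
title: "Methods: Monte Carlo dose verification for circular-collimator beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo dose verification for circular-collimator beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Stereotactic units with variable circular (Iris-type) collimators deliver
small photon fields — projection diameters 5–60 mm at the 800 mm
source–axis distance (SAD). For such fields, analytic effective-path-length
("ray-tracing") dose algorithms remain in routine planning use because they
are fast, but they are known to overestimate dose in low-density media:
scaling depth by the radiological path corrects attenuation while leaving
the water-commissioned scatter and penumbra untouched, and it cannot
represent lateral electronic disequilibrium, which is severe when the
lateral electron range exceeds the field radius (in 0.26 g/cm³ lung tissue
the range is almost four times its water value). An independent Monte Carlo
(MC) dose engine is the standard audit instrument for this failure mode.
`irisdose` implements that audit chain end-to-end at desk scale: a
parameterized phase-space source model with its commissioning corrections,
MC photon transport on voxel phantoms with absolute monitor-unit (MU)
calibration, the effective-path-length comparator commissioned from the
same engine, and the evaluation surface (depth-dose and off-center-ratio
curves, 3D global gamma analysis, dose differences, DVH metrics).

# Source model

The beam is a weighted particle phase space recorded on a plane 400 mm from
the source (beam-local frame: source at z = 0, axis +z). The synthetic
generator draws focal positions from a 2-D Gaussian (`focal_spot_sigma`,
default 1 mm), aims them uniformly into a disc whose projection at 800 mm
is the 60 mm aperture, samples energies from a flattening-filter-free-like
histogram `p(E) ∝ E·exp(−E/0.75 MeV)` on 0.05–7 MeV (mean ≈ 1.5 MeV), and
assigns unit weights. A small halo fraction (default 5%) is aimed into a
wider 65 mm-radius disc, standing in for collimator scatter and leakage so
that the whole 0–60 mm radial-correction domain carries fluence; without
it, the outer correction regions would be empty and the per-region fit
degenerate.

Two corrections reshape the phase space the way a commissioning physicist
would:

* **Radial correction (60 mm collimator).** The projection plane at 800 mm
  is divided into sixty 1 mm annular regions. Fixed-point iteration
  multiplies each region's coefficient by
  `(measured/simulated)^0.7` — the damping exponent 0.7 trades convergence
  speed against oscillation — where `simulated` is the forward water-tank
  OCR at 10 cm depth of the currently corrected phase space. Updates are
  smoothed with a 3-bin triangular kernel and clipped to [0.1, 10].
  Iteration stops when every region's measured/simulated ratio is within
  `tol` (default 0.002) of unity.
* **Aperture correction (smaller collimators).** A hard aperture zeroes
  weights with projection radius beyond R; near-axial particles (direction
  cosine > 0.99) in the bands `[R, R+δR1]` and `[R−δR2, R]` have their
  weights replaced by W1 and W2. The four factors are fitted by coordinate
  descent on the RMS deviation between simulated and measured OCR at 10 cm
  depth, accepting only improving steps (the objective trace is therefore
  non-increasing) and halving step sizes when a sweep stalls.

Both fits run their forward simulations with one fixed seed (common random
numbers). Under Woodcock tracking a particle's trajectory does not depend
on its statistical weight, so measured/simulated ratios taken from the same
seed cancel almost all Monte Carlo noise; the fits behave as if the forward
model were deterministic. This is why the radial fit converges on noiseless
synthetic curves in a handful of iterations and why parameter recovery is
essentially exact.

# Monte Carlo transport

Photons are tracked with Woodcock (delta) tracking: free paths are sampled
from the majorant attenuation (the maximum over the phantom of material
mass attenuation times density at the current energy) and null collisions
re-sampled, which makes heterogeneous grids exactly as cheap as uniform
ones. Real interactions split by the mass-attenuation components of the
local material: photoelectric absorption (energy to a local electron),
Compton scattering sampled from the exact Klein–Nishina density by
composition–rejection (envelope `1/x + x`, acceptance
`1 − x·sin²θ/(1+x²)`), and Rayleigh scattering as a Thomson-shaped
direction change. Photons below 10 keV deposit locally. Pair production is
not modelled — a documented approximation, small for a spectrum that ends
at 7 MeV.

Secondary electrons use a condensed straight-ahead model: twenty steps,
each depositing 1/20 of the initial energy in the current voxel and
advancing by the density-scaled fraction of the CSDA range, with a Gaussian
lateral displacement from a Highland-style multiple-scattering angle at the
mid-step residual energy. Energy is conserved by construction: deposits
plus energy carried out of the grid equal the launched weighted energy, and
the engine asserts the balance to 1e-6 per batch. This model reproduces the
two features the audit needs — build-up (the depth-dose maximum falls near
15 mm) and density-scaled lateral spread (the source of lung-field
disequilibrium) — without claiming Class II condensed-history accuracy.

Scoring is energy per unit voxel mass (dose to medium). Runs are divided
into batches (default 10) with independent, counter-derived random streams
(xoshiro256++ seeded by splitmix64 from `(seed, stream)` with stream
`(beam−1)·batches + batch`); the per-voxel relative uncertainty is the
standard error of the batch mean over the mean, and the scalar summary
averages it over voxels above 50% of the maximum dose. Zero-weight
phase-space particles (collimated out) are excluded from transport and the
result rescaled by their count fraction, so every history is informative
regardless of collimator size.

**Calibration.** The absolute scale is set by the field convention
1 MU = 1 cGy at 800 mm SAD and 15 mm depth in water with the 60 mm
collimator. The engine simulates that geometry (surface at SSD 785 mm) and
averages dose over a cylinder of radius 5 mm and ±3 mm of depth slabs
around the reference point — the depth-dose plateau near the maximum is
flat at that scale, and the cylinder tames the clustered-deposit noise of
the per-voxel estimator. If the region's batch standard error exceeds 2%
the calibration aborts rather than return an unstable factor.

# The ray-tracing comparator

The comparator implements the standard effective-path-length factorization

`D = MU · D_ref · OF(c) · T(d_eff)/A · OCR(r, d_eff) · (SAD/SFD)²`

with `d_eff` the water-equivalent depth from the beam-entry surface (first
voxel above 0.05 g/cm³ along the source ray, exact Siddon traversal), `r`
the off-axis distance scaled onto the SAD plane, and SFD the geometric
source–voxel distance. `T(d)` is the commissioned percent depth dose with
the divergence of its own SSD = 800 mm measurement geometry removed,
`T(d) = PDD(d)/100 · ((800+d)/800)²`. Removing and re-applying the inverse
square explicitly (a Mayneord-style correction) is the only reading under
which the engine reproduces its own commissioning curve exactly at the
commissioning geometry — keeping the divergence inside PDD while also
multiplying by `(SAD/SFD)²` would double-count it. `D_ref` is the same
1 cGy/MU anchor the MC engine is calibrated to, and the denominator `A` is
the same curve product `T·OCR·(SAD/SFD)²` evaluated analytically over the
exact voxel geometry of the calibration reference region, so one MU
delivers exactly the reference dose there, commissioning-curve noise and
all. In water the two engines therefore agree by construction and
heterogeneous differences isolate the effective-path-length approximation. Effective depths beyond the
commissioned PDD range are clamped with a warning; voxels upstream of the
entry surface get zero dose.

Beam data are commissioned from the MC engine itself: per collimator a PDD
at SSD 800 mm, OCR profiles at 15/100/250 mm depth (measurement plane at
800 mm from the source, annulus-averaged on radial regions scaled to that
plane), and a relative output factor at the calibration point against the
60 mm collimator. Because the central-axis disc estimator has heavy,
electron-track-clustered noise, the PDD and output-factor runs use four
times the commissioning history count, PDD curves get depth-adaptive
triangular smoothing (light in the high-curvature build-up, heavier in the
smooth fall-off), and OCR curves use collimator-adaptive radial bins (1 mm
across the penumbra, coarser in the flat interior and the tail) followed by
two smoothing passes and renormalization to the count-weighted inner-5 mm
mean. These are statistical conditioning choices, not physics: they change
commissioning noise, never the expectation.

# Evaluation surface

* **Gamma.** 3D global gamma with absolute dose comparison, normalization
  to the reference maximum, 10% low-dose threshold. For each evaluated
  reference voxel the minimum of
  `sqrt((ΔD/(tol·max))² + (Δr/dta)²)` is taken over a trilinearly
  interpolated neighbourhood sampled every 0.1·dta out to 3·dta. The
  implementation visits offsets in order of increasing distance and stops
  once the distance term alone exceeds the current best — an exact pruning,
  verified voxel-for-voxel against a dense-scan oracle. Because the search
  set is sampled, gamma ordering between different dta values holds only up
  to the sampling discretization; ordering in the dose tolerance at fixed
  dta is exact.
* **ΔD maps** are voxel-wise subtractions on identical grids, optionally
  restricted to a body mask.
* **DVH metrics.** `D_mean` is the structure mean; `D_i` (the minimum dose
  of the hottest i% of the volume) is the `(100−i)`-th percentile with
  linear interpolation of order statistics (R's type-7 convention — the
  convention is not standardized in planning systems, so it is fixed and
  documented here).
* **Curves.** PDD as a disc-averaged central-axis profile normalized to
  100; OCR as a transverse profile normalized to the axis value.

# The lung-slab benchmark

Patient CT cases are replaced by a parameterized phantom: 200 mm cube,
water 50 mm / lung (0.26 g/cm³) 80 mm / water 70 mm along z at 4 mm voxels,
a 10 mm-radius spherical target centered in the lung slab, and three
coplanar beams (0°, ±25°) of 100 MU each. The treatment collimator defaults
to 25 mm — slightly wider than the target, as a planner would choose; a
mismatched smaller collimator would put the whole target into penumbra and
make its mean dose dominated by commissioning noise rather than physics.
The benchmark computes the ray-tracing dose, an MC dose, and an
independent-seed MC replicate, then tabulates pairwise gamma pass rates and
PTV-style D_mean/D_2/D_95 deviations. The expected signature, which the
acceptance suite asserts, is qualitative: ray-tracing minus MC target
D_mean is positive (the low-density overestimation), and the
ray-tracing-vs-MC 2%/2 mm pass rate falls below the MC-vs-independent-MC
rate. An `all_water` switch re-runs the identical plan in a uniform water
phantom, where the two engines must agree (target D_mean within 3%) — the
control that separates the heterogeneity effect from commissioning error.

# What the synthetic data does and does not emulate

The generator defines the study conditions: a 1 mm Gaussian focal spot, the
FFF-like spectrum, the 5% wide-angle halo, unit weights, and the 12 legal
collimator diameters. It emulates the geometric structure of a real
circular-collimator beam — divergence, focal blur, aperture penumbra,
a scatter halo — but not electron contamination, spectral softening
off-axis, or the energy–angle correlations of a treatment head simulation;
"measured" commissioning curves are forward simulations of the same model,
optionally perturbed, smoothed and noised. Passing tests therefore
demonstrate the correctness and internal consistency of the algorithms
(corrections recover known perturbations; engines agree in water; the
heterogeneity signature appears for the physical reason), not agreement
with any physical machine. The physics tables are likewise
model-generated (exact Klein–Nishina incoherent components; anchored power
laws for photoelectric and coherent; water CSDA anchors) — adequate for a
self-consistent audit chain, a few percent from library data at the
extremes.

# Numerical choices and problem sizes

Desk-scale defaults keep every workflow on one CPU core: phase spaces of
2×10⁵ particles, 2.5–5 mm voxels, 10⁵–10⁷ histories depending on the
estimator (calibration and commissioning use the most because their errors
multiply whole dose distributions), batch counts of 2 for common-random-
number fits and 10 wherever uncertainties are reported. The clinical-scale
settings (1 mm grids, 0.5% uncertainty) remain plain configuration. Other
fixed choices: layer boundaries snap to the nearest voxel plane; segments
outside the grid contribute zero path; radial-correction bins are half-open
`[k, k+1)` mm and radii beyond 60 mm are left uncorrected; the W2 band wins
at exactly R; OCR depth dependence is linearly interpolated between
commissioned depths using the effective depth; gamma ties resolve to the
exact minimum of the sampled set.

# Known limitations

* Electron transport is a deposition model, not condensed-history
  transport; backscatter and large-angle electron paths are absent, so
  interface dose gradients are approximate.
* No pair production, no electron contamination, no off-axis spectral
  variation.
* The ray-tracing engine is the generic effective-path-length
  factorization, not any vendor's implementation; comparisons against it
  establish the sign and mechanism of the overestimation, not clinical
  magnitudes.
* Absolute cross sections are model tables; all cross-engine comparisons
  inside the package are self-consistent, but dose values are not traceable
  to a dosimetry protocol.
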