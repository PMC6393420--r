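---
title: "Methods: stress accumulation, thrombogenic footprints, and the annulus surrogate"
author: "dtekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress accumulation, thrombogenic footprints, and the annulus surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtekit)
```

# The model

Device Thrombogenicity Emulation treats a blood-recirculating device as a
stress-dose machine acting on a platelet population.  The raw material is a
set of Lagrangian trajectories: for each seeded platelet, a time series of
position and the six independent components of the viscous stress tensor
sampled along its path through the device.

## Scalar stress

Platelet activation models need a frame-independent scalar measure of the
instantaneous stress state.  `scalar_stress()` uses the von-Mises-type
invariant

$$\sigma = \sqrt{\tfrac{1}{3}\left(\tau_{11}^2+\tau_{22}^2+\tau_{33}^2
  -\tau_{11}\tau_{22}-\tau_{11}\tau_{33}-\tau_{22}\tau_{33}
  +3(\tau_{12}^2+\tau_{13}^2+\tau_{23}^2)\right)}$$

with all three off-diagonal shears entering symmetrically.  Writing the form
this way (rather than privileging any one shear component) is forced by
physics: $\sigma$ must not change when the coordinate axes are relabelled or
the frame is rotated.  Two consequences are used as test oracles throughout:
$\sigma(T + pI) = \sigma(T)$ for any hydrostatic $p$, and
$\sigma(cT) = |c|\,\sigma(T)$.

## Stress accumulation

The per-platelet dose is the path integral of scalar stress over exposure
time,

$$SA = \sum_{i=1}^{N-1} \sigma_i \,\Delta t_i, \qquad
  \Delta t_i = t_{i+1}-t_i,$$

evaluated by the left-rectangle rule exactly as written: each recorded sample
contributes its scalar stress times the step to the *next* sample, and the
final sample contributes nothing.  This makes SA exactly additive over
trajectory concatenation and over any partition of samples into regions —
the property the ROI decomposition relies on.  A trapezoid option exists
(`method = "trapezoid"`) but the rectangle sum is the defining contract and
the default.  Non-uniform steps are supported because exported trajectory
tables may drop samples; with a constant integrand the sum is then still
exact.

SA is always reported in dyne·s/cm² (1 Pa = 10 dyne/cm² exactly).  Internally
the canonical unit is SI (Pa), converted once at the reporting boundary;
`convert_stress_units()` multiplies or divides by 10 in one floating-point
operation, so a round trip is exact to one unit in the last place.

Particles that never leave the domain before the simulation cap keep the SA
accumulated up to their last sample and are *included* by default: the ≥90%
exit requirement in the protocol is a duration criterion, not a filter.
`sa_ensemble(completed_only = TRUE)` restricts to exited platelets when an
uncensored dose is required (for example when comparing against the
closed-form oracle).

## Thrombogenic footprints

The SA ensemble of a device is collapsed into a probability density — the
device's thrombogenic footprint.  `build_footprint()` uses a Gaussian kernel
density estimate on a linear SA grid with Silverman's rule-of-thumb bandwidth
by default (reproducible, no tuning).  SA is non-negative by construction, so
kernel mass leaking below zero (or off the grid) is discarded and the curve
renormalized; every footprint integrates to 1 on its own grid to within
1e-3, and exactly 1 after renormalization.

**Bootstrap equalization.**  Two devices rarely produce the same number of
scored trajectories (seeding counts, exit fractions and ROI occupancy all
differ).  To make footprints comparable, both populations are resampled with
replacement to a common target size (default: the larger population),
`reps = 1000` times by default, and the reported density is the pointwise
mean over replicates.  With a common bandwidth across replicates, the mean of
the per-replicate KDEs is algebraically identical to the KDE of the pooled
resamples, which is how it is computed (one pass instead of a thousand).
Everything is deterministic given the seed, which is recorded in the
footprint object.

**Mode detection.**  `find_modes()` reports local maxima of the density whose
topographic prominence — height above the saddle separating the peak from
higher terrain — exceeds a fraction of the global maximum
(`min_prominence = 0.01` by default).  This suppresses sampling ripple while
retaining genuine secondary and tertiary tail modes, which in a degraded
design mark subpopulations of platelets trapped at high dose.  Grid endpoints
are not eligible peaks.

**Comparison.**  `compare_footprints()` reports the two-sample
Kolmogorov–Smirnov distance on the raw SA values, the main-mode shift between
footprints built on a shared grid and bandwidth (bootstrap-equalized first
when the sizes differ), and the ratio of empirical tail masses beyond a
threshold (50 dyne·s/cm² by default — the "risky" tail).  When both tails are
empty the ratio is 1 (equal exposure); when only the comparison device
populates the tail it is `Inf` with an explicit flag.

## Regions of interest

ROIs are labelled axial bands, optionally restricted radially — the stator,
bearing, impeller-shroud-gap, blade and lower-impeller zones of a real pump
are the motivating examples.  Intervals are half-open, `[min, max)`, so a
sample on a boundary belongs to the downstream region and the set of regions
plus the reserved `"unassigned"` label partitions every trajectory exactly.
Each left-rectangle step is credited to the region containing its *starting*
sample, which makes the per-region SA values sum to the global SA by
construction (to floating-point reordering, ~1e-16 relative).  Two assignment
modes exist: geometric (positions; the default, and the only option for
synthetic data) and zone-label passthrough for CFD exports that carry solver
cell-zone names.  A trajectory contributes one SA value per region it enters;
repeated visits accumulate, matching SA's meaning as cumulative exposure.

# The annulus surrogate

Real VAD flow fields require proprietary geometry and a CFD solver; the
package instead ships an analytic "pump surrogate" in which every stage of
the pipeline has a closed form.  The flow is a steady laminar annular
Couette–Poiseuille field: the inner wall (radius $a$) rotates at $\omega$
(the "impeller"), the outer wall (radius $b$) is fixed, and an axial annular
Poiseuille profile carries the volumetric flow $q$:

$$u_\theta(r) = A r + B/r, \quad
  A = \frac{-\omega a^2}{b^2-a^2}, \quad
  B = \frac{\omega a^2 b^2}{b^2-a^2},$$

$$u_z(r) = k\left(b^2 - r^2 - \frac{b^2-a^2}{\ln(b/a)}\ln(b/r)\right),$$

with $k$ fixed in closed form so that $2\pi\!\int u_z r\,dr = q$.  The only
non-zero cylindrical stress components are the swirl shear
$\tau_{r\theta} = -2\mu B/r^2$ and the axial shear $\tau_{rz} = \mu\,du_z/dr$,
rotated to Cartesian components at each particle's azimuth.  Since $\sigma$
is a rotational invariant, $\sigma(r)=\sqrt{\tau_{r\theta}^2+\tau_{rz}^2}$ is
constant along every streamline, and

$$SA(r) = \sigma(r)\,\frac{L}{u_z(r)}$$

exactly — the oracle against which the advection and quadrature code is
verified to ~1e-14 for exited particles.

**Particles are passive tracers.**  Platelet-sized (~3 µm) particles have a
negligible Stokes number in these flows, so one-way passive advection loses
essentially nothing physically while preserving the closed-form oracle.
`advect()` integrates with fixed-step classical Runge–Kutta (RK4); in this
steady, azimuth-independent field all four stage slopes coincide, so each
step is exact and radius is conserved to machine precision.  When a step
would carry a particle past the outlet plane the step is shortened so the
final sample lies exactly at $z = L$ — the recorded residence time is then
exact, not rounded up to the next full step, which is what lets the
per-particle SA meet a 1e-3 oracle tolerance at the default
$\Delta t = 7.53\times10^{-5}$ s.

**Study conditions.**  The generator defaults emulate a typical DTE run:
9,800 particles seeded area-uniformly (radius drawn as
$r=\sqrt{a^2+u(b^2-a^2)}$, $u\sim U(0,1)$; azimuth uniform) as one upstream
cross-sectional batch; time step 7.53e-5 s; run capped at 0.105 s; blood
analog fluid ($\mu$ = 0.0035 Pa·s, $\rho$ = 1080 kg/m³); benchmark flow
5.3 L/min; inner-wall speed equivalent to 10,600 rpm.  The default geometry
(3/6 mm radii, 30 mm length) was chosen once so that transit times give
roughly 90% exit within the 0.105 s cap and SA magnitudes span ~1–200
dyne·s/cm², the range over which device footprints are typically compared;
`choose_duration()` reproduces the protocol's duration rule (smallest
multiple of $\Delta t$ at which the exit-fraction target, 0.9 by default, is
met).  `seed_config(save_every =)` thins the *recorded* samples without
changing the integration step; with $\sigma$ constant per trajectory the
rectangle sum is unaffected.

**Two-device fixture.**  `two_device_ensembles()` produces a matched pair:
the MAX-like variant re-draws its own seeding and then time-dilates a stated
fraction of its trajectories (default 15%) by a dwell factor (default 8),
emulating platelets caught in the recirculation behind a damaged blade.  SA
is linear under time dilation, so the construction plants a known high-SA
tail — ground truth for footprint comparisons.  The defaults were set so the
recirculating subpopulation lands beyond the 50 dyne·s/cm² tail threshold
under the default operating point.

**Operating-point arithmetic.**  `calibrate_rpm()` emulates the search that
sets impeller speed for a prescribed pressure head on a quadratic pump curve
$H = a\,\mathrm{rpm}^2 - b\,q^2$, by bisection to 1e-8 relative (checked
against the closed form).  `rotations()` and `mass_flow()` are the protocol's
bookkeeping: rev/min × s / 60, and L/min × kg/m³ / 60000.

# PAS/PAR statistics

In vitro, device thrombogenicity is read out as the platelet activation rate:
the slope of the normalized platelet activity state versus recirculation
time.  Two estimators are provided, mirroring common practice:

* `par_pooled()` — average PAS within each sampling time, then one OLS slope
  through the means (time points unweighted by replicate count);
* `par_per_experiment()` — one OLS slope per experiment, reported as
  mean ± SEM.

`compare_par()` reports the fold change (undefined-flagged when the baseline
rate is zero) and, for the per-experiment method, a two-sample t test on the
individual slopes at α = 0.05.  The unequal-variance (Welch) form is the
default for robustness; the classical pooled-variance p-value is reported
alongside.  PAR units are min⁻¹ throughout, since sampling times are in
minutes.  PAS values above 1 are retained with a warning — they are assay
noise, not impossible states.

`simulate_pas()` generates synthetic assays:
`pas = intercept + slope·t + N(0, noise_sd)`, clipped at zero, at the
protocol's sampling times (0/10/20/30 min) with 13 experiments per device.
The defaults — baseline 0.01, noise 0.001 on the normalized PAS scale
(roughly 10% of a typical reading) — represent a clean, well-run assay; with
true rates 8e-5 vs 4e-4 min⁻¹ they give essentially full power at n = 13,
which is what the Monte-Carlo suite verifies (detection rate ≥ 95%, type-I
error within [0.03, 0.07] at α = 0.05 over thousands of replicates).

# Numerical choices

**KDE evaluation.**  Densities are evaluated on the requested grid by the
exact kernel sum when `length(values) × grid points ≤ 5e6`, otherwise by the
binned FFT estimator of `stats::density` computed on an internal grid of at
least 2¹³ points (bin width far below any usable bandwidth) and interpolated
onto the target grid.  The two paths agree to ~1e-6 absolute, so mixing them
across a comparison is harmless.

**Comparison smoothing scales.**  The SA density of the annulus surrogate has
an integrable inverse-square-root singularity at the radius where $SA(r)$ is
minimal (a generic feature of any smooth flow map with an interior minimum).
Near such a peak, a rule-of-thumb bandwidth resolves sampling noise rather
than structure: the pointwise sampling deviation of a KDE is approximately
$\sqrt{f(x)\,R(K)/(n h)}$ with $R(K)=1/(2\sqrt{\pi})$.  Oracle and
convergence comparisons in the test suite are therefore run at a fixed
smoothing scale chosen so that this deviation sits well below the 5%-of-peak
tolerance being verified: $h = 0.5$ dyne·s/cm² for $n \approx 10^4$ samples
and $h = 16$ dyne·s/cm² for the 500-sample equalization check.  At $n = 500$
this is close to the information limit — no bandwidth makes a 500-point
density agree with the population much better than ~3% of peak in sup-norm —
so the equalization check should be read as "the bootstrap adds no
distortion at the scale a 500-point sample can resolve".  Silverman's rule
remains the default for *reporting* footprints, where no cross-sample
sup-norm claim is being made.

**Ties and degenerate inputs.**  Top-k trajectory ranking breaks SA ties by
particle id ascending.  A constant SA sample has no Silverman bandwidth; the
error message asks for an explicit one.  Trajectories with fewer than two
samples stay in the ensemble (they count toward seeding and exit statistics)
but are excluded from SA scoring with a warning.  Empty ROIs are omitted with
a warning rather than producing empty footprints.

**Determinism.**  Every stochastic operation (seeding, bootstrap, PAS
simulation) takes an explicit seed, uses it locally, and restores the global
RNG state afterwards; `run_demo()` writes byte-identical artifacts on
identical configuration + seed, and records both in its manifest.

# What the surrogate does and does not emulate

The annulus reproduces the *structure* of a DTE analysis — area-uniform
seeding, stress sampling along trajectories, a broad SA distribution with a
sharp main mode and a long residence-time tail, exit-fraction duration logic,
and a two-device contrast with a known tail difference.  It does not emulate
turbulence (the field is laminar and steady), secondary flows, blade-passing
unsteadiness, two-way particle coupling, or the geometry of any real pump;
its absolute SA values and mode locations are properties of the chosen
annulus, not predictions for any device.  Tests passing on the surrogate
therefore certify the *post-processing chain* — quadrature, unit handling,
footprint statistics, ROI bookkeeping — not the hemodynamics of a particular
VAD.  Likewise the PAS generator assumes linear activation growth with
Gaussian assay noise; real assays show donor-to-donor variability and mild
nonlinearity that the package's statistics tolerate but the generator does
not model.

# Problem sizes used by the test and acceptance suites

Full-scale checks use 9,800–10,000 particles at the default time step
(oracle agreement, footprint convergence), 1,000 Monte-Carlo replicates for
PAR power and 2,000 for type-I error, and 10,000-sample KDE checks; unit and
property tests run on ensembles of tens of particles.  The complete test
suite runs in about a minute on one CPU; `scripts/acceptance.R` in well
under a minute.
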