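# dtekit — Device Thrombogenicity Emulation for blood-recirculating devices

Implantable blood pumps (ventricular assist devices, VADs) expose circulating
platelets to supraphysiologic shear.  The cumulative shear history a platelet
collects while traversing a device is what drives it toward activation — and
the device toward thrombosis.  **Device Thrombogenicity Emulation (DTE)**
scores a candidate design by following a large population of platelets through
the computed flow field, integrating each one's stress exposure, and comparing
the resulting *stress-accumulation distributions* between design variants.

`dtekit` is the computational core of that workflow for R users: it takes
Lagrangian platelet trajectories (position + viscous stress tensor per time
step, as exported from a CFD discrete-phase run), and produces the statistics
a thromboresistance study needs.  It is aimed at cardiovascular-device CFD
engineers and the biostatisticians who analyse their outputs.

## What it computes

**Scalar stress.**  The six components of the symmetric viscous stress tensor
are collapsed into a von-Mises-type rotational invariant

    σ = sqrt( (τ₁₁² + τ₂₂² + τ₃₃² − τ₁₁τ₂₂ − τ₁₁τ₃₃ − τ₂₂τ₃₃
               + 3(τ₁₂² + τ₁₃² + τ₂₃²)) / 3 )

so that a pure shear τ gives σ = τ and any hydrostatic part cancels exactly.

**Stress accumulation (SA).**  Along each platelet trajectory,

    SA = Σᵢ σᵢ · Δtᵢ      [dyne·s/cm²]

the left-rectangle time integral of scalar stress — the per-platelet
thrombogenic dose.

**Thrombogenic footprints.**  The SA values of the whole seeded population are
collapsed into a probability density function (Gaussian KDE).  Populations of
unequal size are made comparable by bootstrap resampling to a common target
size.  Footprints are compared by Kolmogorov–Smirnov distance, main-mode
shift, and the mass of the risky tail (SA > 50 dyne·s/cm² by default); density
modes are detected by topographic prominence.

**Regions of interest.**  Trajectory segments are assigned to labelled axial
(optionally radial) regions — stator, bearing, blade, gap, … — producing
per-region SA ensembles and footprints whose sum reconstructs the global SA
exactly.

**Synthetic pump surrogate.**  An analytic annular Couette–Poiseuille flow
(rotating inner wall + axial pressure-driven flow) with particle advection.
Scalar stress is constant along each streamline, so every particle's SA has
the closed form σ(r)·L/u_z(r): the entire pipeline is verifiable against an
exact oracle, without any CFD software.  Operating-point arithmetic
(impeller-speed calibration for a target pressure head, revolutions, inlet
mass flow) is included.

**Platelet activity statistics.**  For in vitro recirculation-loop assays,
the platelet activation rate (PAR) is the fitted slope of platelet activity
state (PAS) versus time — pooled across experiments or per experiment with
SEM — with two-device comparison (fold change, Welch t test).

## Worked example

Simulate ~2,000 platelets through the default annulus surrogate (3/6 mm radii,
30 mm long, 10,600 rpm, 5.3 L/min, blood-analog fluid) and score them:

```r
library(dtekit)

cfg <- annulus_config()
sc  <- seed_config(n_particles = 2000, seed = 1)
ens <- advect(cfg, seed_particles(cfg, sc), sc)
exit_fraction(ens)
#> [1] 0.8965

sa <- sa_ensemble(ens)
sa
#> <dte_sa> annulus: 2000 of 2000 particles scored, SA range [0.871, 14] dyne.s/cm2

top_sa_trajectories(ens, 3)
#>   particle_id       sa
#> 1        1978 13.98407
#> 2        1916 13.96390
#> 3         891 13.95015

fp <- build_footprint(sa)
find_modes(fp)[1, ]
#>   location    height prominence
#> 1 1.087659 0.5125697  0.5022282
```

About 90% of the seeded platelets exit within the default 0.105 s run, each
carrying an SA dose of roughly 1–14 dyne·s/cm²; the footprint's main mode
sits near 1.1 dyne·s/cm² (fast mid-gap transits), with the tail made of
slow near-wall passages.

Compare a baseline ("MIN-like") design against a degraded ("MAX-like")
variant that traps 15% of its platelets in slow recirculation:

```r
pair <- two_device_ensembles(cfg, seed_config(n_particles = 2000, seed = 1,
                                              max_duration = 2, save_every = 25))
compare_footprints(sa_ensemble(pair$min), sa_ensemble(pair$max),
                   threshold = 50, seed = 1)
#> <dte_footprint_comparison>
#>   KS distance:           0.1335
#>   main mode shift (b-a): 0 dyne.s/cm2
#>   tail mass > 50:        a = 0.018, b = 0.0405 (ratio 2.25)
```

The degraded variant more than doubles the fraction of platelets beyond the
50 dyne·s/cm² tail threshold while leaving the main mode in place — the
signature of added recirculation rather than globally higher shear.

A command-line front end (`inst/cli/dte.R`) exposes `simulate`, `footprint`,
`roi`, `compare`, `pas` and `demo` subcommands; `run_demo()` executes the
whole two-device pipeline and writes all CSV/JSON artifacts plus a
reproducibility manifest.

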