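---
title: "Modelling flat-probe puncture of layered fruit tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flat-probe puncture of layered fruit tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puncturesim)
```

## The problem

The firmness of soft fruit such as papaya is routinely measured with a
puncture (Magness–Taylor style) test: a small flat-ended cylindrical probe —
here 2 mm in diameter — is driven into the intact fruit at a constant speed
while force and insertion depth are recorded. The curve rises roughly
linearly until the skin starts to rupture at the **bioyield point** (the
first force peak), drops sharply as the probe breaks through, and then
fluctuates around a plateau while the tip ploughs through the flesh. The
bioyield force and the deformation at which it occurs track ripening and
post-harvest storage, so a mechanistic model that predicts them from
independently measured tissue properties is useful both for understanding
wounding during handling and for instrument design.

`puncturesim` implements a desk-scale finite-element model of this test for
a two-layer tissue (a thin, stiff skin bonded to much softer flesh),
together with everything needed to exercise it end to end: property-derivation
formulas, a synthetic-data generator with the statistical structure of real
puncture records, bioyield extraction, parameter calibration by inverse
analysis, a sensitivity study, and a validation pipeline against a packaged
table of measured bioyield forces for three storage days (0, 4, 7) and three
probe speeds (1.5, 2, 2.5 mm/s).

## Constitutive model

Both tissues follow a bilinear elastoplastic law: linear elastic with
modulus $E$ up to the yield stress $\sigma_y$, then linear isotropic
hardening with tangent modulus $E_t$ (perfectly plastic as $E_t = 0$). In
multiaxial form this is J2 (von Mises) plasticity with hardening modulus
$H = E E_t / (E - E_t)$, integrated with the standard radial-return map and
consistent tangent. The uniaxial response of the return map reproduces
`bilinear_stress()` to near machine precision (the test suite drives a
single integration point along a uniaxial stress path and checks this to
1e-8).

Two auxiliary formulas convert routine laboratory measurements into model
inputs. Moisture content is the oven-drying mass loss
$MC = (w_1 - w_2)/w_1 \times 100$, and Poisson's ratio interpolates between
a fully dried value of 0.1 and a fully fresh value of 0.5:
$\nu = (0.5\,MC + 0.1\,(100 - MC))/100$, so a typical fresh-tissue moisture
of 85% gives $\nu = 0.44$. Density comes from the mass and dimensions of a
cylindrical plug. The written form of the interpolation is the only reading
consistent with the stated endpoint meanings, and it lands inside the
measured 0.43–0.45 range at realistic moisture; that is why it was adopted.

The packaged `material_levels()` table carries the measured min/avg/max
levels per tissue (skin: $E$ 2–15 MPa, $\sigma_y$ 0.5–4 MPa, $E_t$
0.02–0.04 MPa; flesh: $E$ 0.5–4 MPa, $\sigma_y$ 0.05–1.8 MPa, $E_t$
0.002–0.004 MPa; both: $\nu$ 0.43–0.45, $\rho$ 1000–1200 kg/m³). These
levels bound every calibration search and parameterise the sensitivity
study.

## Geometry, mesh, and why the model is axisymmetric

The reference experiment models a 15 × 20 mm tissue cross-section under the
probe with a 1 mm skin layer. Since the load (a central circular flat punch
on a layered half-space, fixed base) is axisymmetric, the package reduces
the problem to a 2D axisymmetric section: radius 15 mm, depth 20 mm, skin
band 1 mm, probe radius 1 mm. This is the standard desk-scale reduction of
this configuration; it preserves the contact mechanics while cutting the
cost by orders of magnitude relative to a 3D tetrahedral model. The skin is
meshed as a thin band of solid elements (at least two rows through the
thickness) rather than shells tied to solids — a conforming structured grid
makes the tie constraint automatic.

`build_mesh()` produces a graded structured quadrilateral mesh: element
edges at most `target_h` under the punch footprint ($r \le 2a$) and through
the skin, growing geometrically up to `refinement_ratio` times the finest
spacing towards the far boundaries. The grading rule caps the coarsest cell
at the ratio times the *finest* spacing, which also bounds the element
aspect ratio by the ratio. The published mesh statistics of the 3D
reference model (4 557 nodes / 18 066 tetrahedra) are mesher-specific and
are not reproduction targets; the default axisymmetric mesh has a few
hundred quadrilaterals, and a mesh-halving consistency check (< 5% change
in the pre-bioyield force curve) is part of the test suite.

## Solvers

Units are mm–N–MPa–s throughout the solver core, with density converted to
tonne/mm³; this is the conventional explicit-FE unit discipline and keeps
forces in newtons without scale factors.

**Quasi-static (default).** Displacement-controlled punch increments
(default 0.02 mm) with full Newton iteration and the consistent
elastoplastic tangent; a backtracking line search on the residual norm
stabilises the iterations across contact-set changes and erosion events.
Bottom face fixed, radial displacement fixed on the axis and the outer
radius. Contact with the rigid flat punch is frictionless penalty contact
on the exposed surface nodes under the punch face; the penalty stiffness is
auto-scaled to 100 times the adjacent element column stiffness, which keeps
the penetration error around 1% of an element at the default setting (the
patch test in the suite uses a $10^6$ scale to reach 1e-6 exactness).
Friction is omitted because nothing in the reference data constrains it.

**Erosion.** Material failure is represented by element erosion: any
element whose maximum integration-point equivalent plastic strain reaches
`epsp_max` (default 0.5, closed threshold) is permanently deleted and its
stress zeroed, after which equilibrium is re-established at the same punch
depth (the deletion may cascade). Newly exposed nodes become contact
candidates, which is what lets the punch break through the skin — the
force drop at that event *is* the simulated bioyield. The reference
workflow relies on the same mechanism but never states its trigger;
an equivalent-plastic-strain threshold is the simplest criterion consistent
with a plasticity-based material model, and it is exposed to calibration.

**Explicit dynamics.** A central-difference integrator with lumped mass,
the same stress update, contact and erosion operators, mass-proportional
damping, and a smooth-start velocity ramp (default: the first 5% of the
run) that suppresses the startup impact transient. The stability limit uses
the constrained-modulus wave speed plus the contact-spring frequency; the
exported `stable_time_step()` gives the conventional bar-wave hand estimate
$\Delta t \le 0.9\,h/\sqrt{E/\rho}$. Because the constitutive law is
rate-independent, probe velocity influences the result only through
inertia. Real probe speeds (1.5–2.5 mm/s) are quasi-static for all
practical purposes, so explicit runs expose a `time_scale` factor that
scales the punch velocity; at moderate scaling (≈ 200×) the explicit and
quasi-static solutions agree on the bioyield point to a few percent, and at
aggressive scaling (≈ 1000×) inertia visibly raises the recorded peak with
probe speed — the qualitative trend the experimental velocity series shows.
The velocity contradiction in the reference description (10/20/30 mm/s in
the simulation section versus 1.5/2/2.5 mm/s everywhere else) is resolved
in favour of the experimental speeds, which the validation table uses.

Locking: at $\nu \approx 0.44$ bilinear quads lock volumetrically, so both
solvers use mean-dilatation B-bar (selective reduced integration of the
volumetric term). The flat-punch stiffness of the elastic half-space
($F = 2 E^* a\,\delta$) is reproduced within 10% on the shipped
convergence-test mesh, and without B-bar it is not — that closed form is
the locking check in the suite.

Both solvers are fully deterministic: identical configurations give
bit-identical results, asserted in the tests.

## Bioyield extraction

`detect_bioyield()` operationalises the observational definition (the first
peak at which the probe starts to break through): the first local maximum
of the moving-average smoothed force (window 5 samples) whose subsequent
drop — before the force first exceeds that maximum again — is at least
`drop_fraction` (default 5%) of the peak. The reported force/deformation
pair is read off the *unsmoothed* record at the raw argmax within a window
of the detected peak, so noise-free synthetic peaks are recovered exactly.
Both knobs are exposed; the defaults are the smallest values that ignore
the plateau fluctuation of the synthetic generator at its default
amplitude. If no qualifying drop exists the curve is flagged
(`rupture_detected = FALSE`) and the global maximum is reported.

## Synthetic data

The generator emulates the three empirical features of puncture records:
a linear rise to the bioyield peak, a sharp drop over a short ramp
(0.15 mm), and a fluctuating plateau (bounded sinusoid plus multiplicative
Gaussian noise) with no systematic trend, sampled at 200 points/s with
depth = velocity × time. When the uniform sampling grid misses the exact
bioyield depth the exact peak sample is inserted, so the generator/detector
round trip is exact at zero noise for every measured (force, deformation)
pair. Property samples are drawn from independent truncated normals
(truncated to each field's validity range, with $E_t$ additionally
truncated below the drawn $E$), matching data reported as mean ± standard
error; the reference study reports no higher moments, so any heavier-tailed
model would be invention. All generators are pure functions of (spec, seed)
and restore the global RNG state.

What the generator does **not** emulate: probe-size effects, temperature,
viscoelastic relaxation, and correlated within-fruit property variation.
Tests that pass on synthetic data therefore validate the pipeline's
plumbing and the detector's contract, not the biology.

## Calibration and validation

Per-day material parameters are calibrated by inverse analysis, mirroring
the reference study's procedure of adjusting uncertain inputs until the
simulation matches the measured bioyield forces. `calibrate()` runs
deterministic coordinate descent over bounded grids (memoised, fixed sweep
order, budget-limited; default 60 evaluations per day). The default search
adjusts skin yield stress and modulus and flesh modulus and yield stress
within the measured min–max ranges, starting from the mid (avg) level;
parameter sets that never rupture within the insertion range are rejected
outright, since they cannot reproduce the experiment regardless of the
force they reach. Calibration sweeps run at a coarser depth increment
(0.05 mm) than the final validation runs (0.02 mm); the mesh-consistency
check bounds the transfer error.

The storage-day mapping (day 0 → max level, day 4 → avg, day 7 → min) is a
default, not a claim: all measured properties decline with storage, but the
printed levels are pooled extremes, not day-wise means, so the mapping only
seeds the fixed (non-searched) fields and the calibration does the rest.
Because the quasi-static model is rate-independent, one simulation per day
covers that day's three velocities; the validation records replicate it per
velocity with the time column alone differing.

Validation compares simulated against measured bioyield force with the
relative-error statistic $RE = |X_E - X_F|/X_E \times 100$. With the
shipped defaults the calibrated model keeps every force error below 15%
(the acceptance suite asserts exactly this); deformation errors are
reported but not gated — like the reference model, the simulation
systematically over-predicts the bioyield deformation, which the reference
authors attribute to geometric idealisation.

## Problem sizes

The shipped default study uses the 0.5 mm mesh (≈ 180 elements), 0.02 mm
validation increments, 0.05 mm calibration increments, a 3 mm insertion
range, and a 60-evaluation calibration budget per day. These sizes were
chosen so a full calibrated validation completes in minutes on a single
core while staying inside the < 5% mesh-consistency band; halving the
element size or the increment changes the headline errors by far less than
the 15% gate.

## Known limitations

* Small-strain kinematics on the frozen reference geometry; erosion stands
  in for material failure and large-deformation remeshing. Insertion depths
  at bioyield (≈ 1.5–2.3 mm) keep pre-rupture strains moderate, but
  post-rupture plateau forces are qualitative.
* The erosion threshold is a single scalar; no damage evolution, no mesh
  regularisation of the softening. Bioyield forces are therefore weakly
  mesh-dependent (bounded by the consistency test), and plateau behaviour
  more so.
* The sensitivity contrast between the all-maximum and all-minimum property
  levels is much larger in this model (≈ 90% force decrease) than the
  ≈ 52% (19 → 9 N) reported for the reference model. The deformation
  contrast (≈ 1.45 mm up to ≈ 2 mm from min to max level) *does* reproduce.
  A force ratio of only ≈ 2 between parameter sets whose yield stresses
  differ eightfold would require a failure mechanism largely insensitive to
  the yield stress, which contradicts both this model and the reference
  model's own strong day-to-day force trend; the package reports what its
  mechanics produce rather than tuning toward the printed contrast.
* Viscous damping in the explicit driver is uncalibrated (nothing in the
  reference data constrains it); it defaults to zero and exists for noise
  control.
* The published contact-stress value (0.71 MPa) has no stated definition
  (nominal vs von Mises, averaging area) and is not asserted; peak von
  Mises stress is available from field snapshots. The pairing behind the
  published velocity-difference fits is likewise unstated, so
  `fit_velocity_effect()` implements the functional form generically and
  the examples reproduce the forms, not the unstated data pairing.
* Engineering stress/strain measures are assumed for specimen-level curve
  conversion; the reference gives no conversion details.

## A worked micro-example

```{r example, eval = FALSE}
mesh <- build_mesh(domain_spec(), target_h = 0.5, refinement_ratio = 4)
mats <- list(skin = material_level_params("skin", "avg"),
             flesh = material_level_params("flesh", "avg"))
res <- solve_quasi_static(mesh, mats,
                          probe_spec(velocity = 1.5, max_insertion = 3),
                          solver_config("quasi_static"))
detect_bioyield(res$curve)
#> Bioyield: F = 17.26 N at d = 2.28 mm (rupture detected)
```

The full study is one call, `run_validation(default_config())`, and the
command-line front end (`inst/cli/puncturesim.R`) exposes `simulate`,
`validate`, `calibrate`, `synth` and `metrics` subcommands over the same
functions.
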