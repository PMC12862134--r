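---
title: "Methods: IRE field simulation, dose planning, and response quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IRE field simulation, dose planning, and response quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irecar)
```

`irecar` models irreversible electroporation (IRE) dose planning for
subcutaneous tumors and quantifies treatment response in vitro (tumor
spheroids) and in vivo (caliper/survival data). This vignette documents
the models, their assumptions, the tunable parameters, and the numerical
and design choices, in the order the pipeline runs them.

## 1. The quasi-static field model

During a microsecond pulse the tissue behaves resistively, so the
potential obeys the steady current-conservation equation

$$\nabla \cdot (\sigma \nabla \varphi) = 0,$$

with conductivity $\sigma$ (S/m), Dirichlet potentials $\pm V/2$ on the
two needle electrodes, and an insulating outer boundary. The dose metric
is the field magnitude $|E| = |\nabla\varphi|$ in V/cm.

**Assumptions.** Conductivity is static: no electroporation-induced
conductivity rise, no Joule heating, no transient waveform — the pulse
scheme (90 × 90 µs at 1 Hz) is carried as metadata only. The tumor is a
homogeneous sphere in homogeneous background tissue; skin and fat
layering is collapsed into the single background compartment because the
planner randomizes conductivities over ranges rather than fixing layer
values. These simplifications bias the absolute field pattern, which is
why the planner treats conductivities as random, not known.

**Discretization.** Regular Cartesian voxels (default 0.25 mm), 7-point
finite differences. Face conductivities are harmonic means of the two
adjacent cells, which keeps the normal current continuous across the
tumor/background jump — arithmetic averaging would leak current through
the interface. Electrode voxels carry a large conductivity so the
surface potential is pinned at the electrode face rather than the cell
center; this measurably improves agreement with the analytic two-wire
solution near the needles.

**Geometry.** Needles are rasterized as solid cylinders of radius
0.5 mm (a typical preclinical needle; the diameter is a configuration
choice), axes along z, exposed length defaulting to the tumor diameter
so the active length spans the tumor. The domain extends 4 electrode
spacings in every axis, at which the insulating boundary perturbs the
inter-electrode field by well under a percent; a thin z-slab is allowed
only when the needles penetrate the whole depth, making the solution
z-invariant (the configuration used for the hydrogel phantom and for
validation against the two-dimensional two-wire formula).

**Solver.** The symmetric positive-definite system is solved by
conjugate gradients with an SSOR(1) preconditioner, zero initial guess,
relative residual tolerance $10^{-6}$ and an iteration cap of 50,000.
Non-convergence is an error, never a silently degraded field.
`solve_field()` records the residual and iteration count in the result.

**Validation invariants** (all asserted in the test suite): midpoint
agreement with $E = 2V/(d\,\ln((d-a)/a))$ within 5% at 0.1-mm
resolution with the error decreasing under refinement; exact linearity
in $V$; invariance under global rescaling of $\sigma$; mirror symmetry
across the inter-electrode midplane; electrode current balance within
1%.

## 2. Threshold calibration from hydrogel lesions

Cell-laden collagen hydrogels map a field distribution to a visible
live/dead boundary. Because the gel is a uniform phantom, the same
needle-pair solver with a single conductivity gives the field, and the
measured lesion boundary inverts directly to the lethal threshold:

* **extent mode** (default): the lesion width along the inter-electrode
  axis is a caliper-like measurement; the threshold is $|E|$ at distance
  extent/2 from the midpoint, read from the axis profile by linear
  interpolation.
* **area mode**: for imaging-based readouts, the threshold is the
  isocontour level whose enclosed equatorial-plane area equals the
  measured lesion area (computed exactly as the k-th largest voxel value,
  k = area / voxel area — equivalent to bisection on the level but
  without iteration).

The hydrogel conductivity value is irrelevant to the inversion (the
field is conductivity-scale invariant in a homogeneous medium); the
drive voltage and spacing must simply place the threshold isocontour on
the decaying branch of the profile, beyond the needles, where the
field–extent relation is monotone. Inversion inside the needle pair is
ill-posed (the profile is non-monotone there) and the generator and
inversion therefore work on the outer branch only. Replicate thresholds
aggregate to mean, sample SD, minimum, maximum — no hierarchical model,
matching how such calibrations are conventionally reported.

Parameter recovery is verified by simulation: 100 repeats of a
5-replicate experiment with 5% extent noise around a 500 V/cm truth must
show mean bias below 2% and 2-SD coverage of the truth in at least 90%
of repeats.

## 3. Monte-Carlo dose planning

A treatment is planned for a *population* of plausible tumors rather
than one nominal case. Each scenario draws:

| parameter | distribution | default | rationale |
|---|---|---|---|
| tumor diameter | U(4, 8) mm | — | the subcutaneous size range at treatment |
| electrode spacing | diameter − 1 mm | — | needles inserted just inside the tumor margin |
| tumor conductivity | U(0.1, 0.5) S/m | — | literature-typical soft-tumor range |
| background conductivity | U(0.02, 0.2) S/m | — | subcutaneous fat-dominated tissue |
| lethal threshold | Normal(525, 77) truncated to [442, 613] V/cm | calibrated estimate | propagates calibration uncertainty |

The conductivity ranges are modeling defaults, not measured values; they
are exposed in `planning_ranges()` and their influence is what
`plan_sensitivity()` tabulates. A `threshold_fixed` switch reproduces
mean-only planning, and `"worst_case"` plans against the calibrated
maximum (613 V/cm).

For each scenario the field is solved **once at unit voltage**; coverage
at every candidate ratio follows by exact linear scaling (linearity of
the Laplace problem, itself an asserted invariant). This makes coverage
trivially non-decreasing in the ratio and cuts the plan's cost to one
solve per scenario. Candidate ratios default to 1,000–3,000 V/cm in
500-V/cm steps — the coarsest grid that brackets the clinically used
range; the step is configurable and its effect belongs in the
sensitivity table.

"Fully ablate" is operationalized as coverage exactly 1.0 of
tumor-labeled voxels at planning resolution: every tumor voxel at or
above threshold. `select_dose()` picks the smallest candidate ratio at
which all scenarios reach 1.0, and flags the plan incomplete (returning
the largest candidate) if none does. Per-scenario applied voltage is
ratio × spacing.

Default problem sizes — 30 scenarios on the 0.25-mm grid (domains up to
113³ voxels) — run in under a minute on one CPU; the sensitivity table
uses a 0.5-mm grid because it needs six full plans and the selection,
not the field detail, is what is being probed.

## 4. Spheroid quantification

The in-vitro readout is a two-channel time-lapse: eGFP (tumor
viability) and CellTracker Deep Red (CAR T cells). The hand-drawn
regions of interest of the bench workflow are replaced by a
deterministic segmentation: Gaussian smoothing (σ = 2 px), Otsu
threshold on the range-rescaled image (making the mask invariant to
affine intensity changes), largest connected component, hole filling. A
constant image yields a flagged empty mask rather than an error.
Externally drawn masks can be passed directly to `frame_metrics()` for
parity with manual workflows.

Net intensities are inside-mask minus background means; the background
region excludes a 10-px dilation of the mask so the peri-spheroid halo
(and the CAR-T ring that forms around spheroids) does not contaminate
it. The deep-red channel is measured inside the *green-derived* mask —
that is precisely what makes it an infiltration metric. Tracks are
normalized to each spheroid's own pre-treatment frame (the first
timepoint); a plate-level baseline can be supplied instead via the
`baseline` argument, since either convention is defensible and the
choice matters when pre-treatment frames are missing.

XTT absorbances use the subtraction form A475 − A660 of the
reference-wavelength correction (the conventional reading of
"normalized using" for this assay); a ratio mode is provided for
workflows that prefer it.

## 5. In-vivo metrics and survival

Caliper volume is $V = 0.5\,L\,W^2$ with $L \ge W$ (swapped inputs are
reordered with a warning). Treatment triggers strictly above 100 mm³;
the humane endpoint fires at 12 mm in any direction.

Response classification works on the measurement schedule, not calendar
time: "eradicated within 48 h" means volume zero at the first scheduled
measurement at or after treatment day + 2, because thrice-weekly
measurement cannot observe the true eradication instant. Progression-free
survival is defined operationally as time from treatment to the first
progression (volume exceeding the pre-treatment value) or recurrence
(first positive volume after eradication), censored at the end of
follow-up (day 60); overall survival is time from treatment to
death/euthanasia, censored likewise. These operational definitions are
implementation choices — study protocols rarely state them exactly —
and are isolated in `classify_response()` / `survival_tables()` so they
can be swapped.

Kaplan–Meier curves and log-rank tests delegate to the survival package
(ties handled by the standard simultaneous risk-set convention); the
test suite checks the estimator against a hand-computed product-limit
table and the log-rank statistic against a direct
hypergeometric-variance evaluation, so the wrapper cannot drift from
the textbook definitions. Pairwise p-values are Bonferroni-corrected
with k = number of pairs (6 for 4 arms), capped at 1. A pair with no
events in either arm has a degenerate (0/0) log-rank statistic and is
reported as statistic 0, p = 1.

## 6. What the generators emulate — and what they do not

Every generator is a pure function of its arguments and a seed.

**Dose–response.** Viability after a uniform-field exposure follows
$v(E) = v_0\,(1 + e^{-m/w})/(1 + e^{(E-m)/w})$ with baseline
$v_0 = 0.9499$, midpoint $m = 800$ V/cm and width $w = 360$ V/cm. The
anchors are the measured suspension viabilities (~95% untreated, ~34% at
1,000 V/cm, ~3% at 2,000 V/cm): solving the two treated anchors fixes
$m \approx 795$ and $w \approx 362$, rounded to 800/360. Note the
suspension midpoint is substantially higher than the ~525 V/cm
lesion-boundary threshold — a single plain logistic centered at the
lesion threshold cannot pass through the treated anchors, and the two
numbers measure different things (a sharp in-gel kill boundary versus
graded single-cell suspension viability), so the model is anchored to
the suspension data it emulates.

**Hydrogel lesions.** The truth isocontour's axis extent is perturbed
multiplicatively, extent × (1 + ε), ε ~ N(0, cv). This models caliper
reading error only — not staining chemistry, cell-density effects, or
boundary diffuseness.

**Spheroids.** Disk-shaped spheroid, green intensity proportional to
the viable fraction; post-IRE swelling increases with field; viable
fraction rebounds (saturating exponential toward 60% of the deficit)
when the field is ≤ 1,500 V/cm without CAR-T; CAR-T erodes the radius
from the boundary and contributes deep-red signal in a surrounding ring
plus a programmed infiltration fraction inside the mask — early
infiltration only when combined with IRE. Pixel noise is Poisson shot
noise plus Gaussian read noise. Magnitudes of swelling, erosion and
infiltration are free parameters chosen to be visually and numerically
plausible; only their *orderings* (control > sub-lethal rebound >
lethal ≈ combination at 72 h; infiltration increasing over time in the
CAR-T-only arm) are contracts, because the underlying study reports
those patterns, not calibrated magnitudes.

**Cohorts.** Exponential growth with per-animal lognormal rate
heterogeneity (median 0.14/day, sdlog 0.15, chosen so tumors trigger
treatment around four weeks and reach the 12-mm endpoint well inside
follow-up); CAR-T-only growth slowed by factor 0.85; IRE and combination
arms eradicate at the first measurement ≥ 48 h post-treatment; IRE-only
recurs with probability 4/6 after a uniform 10–25-day delay;
combination never recurs; calipers derive from volume assuming a 1.2:1
axis ratio with 5% multiplicative noise.

Passing tests on these generators demonstrates that the *analysis
machinery* is correct and self-consistent (pipeline closure: the
analysis recovers exactly what was programmed). It does not demonstrate
that real tumors grow exponentially, that real spheroids are disks, or
that the dose–response of any other cell line matches the anchors — the
generators are phenomenological emulators for testing, not biological
models.

## 7. Numerical details and degenerate inputs

* Zero applied voltage short-circuits the solve and returns an exactly
  zero field.
* Overlapping needles (spacing ≤ diameter), tumors larger than the
  domain, resolutions coarser than the needle radius, non-positive
  conductivities, and empty electrode rasterizations are all rejected
  with specific errors.
* A single calibration replicate reports SD 0 (not NA), with
  min = mean = max.
* Lesion extents beyond the grid, or isocontour levels outside the
  attainable range, error rather than extrapolate.
* Coverage ties: `select_dose()` breaks ties toward the *smallest*
  ratio, and "complete" means coverage ≥ 1 within exact voxel counting
  (no epsilon).
* Truncated-normal threshold draws use rejection sampling; with SD 0
  the draw is the mean exactly.
* All generator randomness is scoped: the global RNG state is saved and
  restored, so generators do not perturb user code.

## 8. Known limitations

* Static conductivity understates the field redistribution that
  electroporation itself causes during a pulse train; the planner
  compensates only by randomizing σ.
* The voxelized needle surface is a staircase; sub-voxel electrode
  placement effects appear below ~2 × the voxel size.
* Coverage at exactly 1.0 depends on the planning resolution: a finer
  grid resolves thinner under-treated shells at the tumor rim. The
  0.25-mm default matches the needle-radius scale; re-run
  `plan_sensitivity()` when changing it.
* The spheroid segmentation assumes one dominant object; debris
  comparable in size to the spheroid would defeat the
  largest-component rule.
* PFS/OS definitions are operational choices (see §5) and should be
  restated when comparing against studies that define them differently.
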