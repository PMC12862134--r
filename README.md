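# irecar

Treatment planning and response quantification for irreversible
electroporation (IRE) tumor ablation combined with CAR T-cell therapy.

IRE ablates tissue nonthermally: microsecond high-voltage pulses applied
through needle electrodes permeabilize cell membranes beyond recovery
wherever the local electric field exceeds a cell-line-specific **lethal
threshold** E_lethal (V/cm). Planning a treatment therefore reduces to a
field problem: choose the applied voltage so that the entire tumor sees
|E| ≥ E_lethal. `irecar` implements that workflow for preclinical
subcutaneous-tumor studies, together with the downstream in-vitro and
in-vivo response quantification, and ships seeded synthetic-data
generators so every stage can be exercised and tested without any
experimental data.

**Who it is for:** researchers designing or analysing preclinical
electroporation / adoptive-cell-therapy studies who need a transparent,
scriptable alternative to commercial FEM planning plus a reproducible
analysis pipeline.

## What it computes

1. **Electric-field simulation** (`build_domain()`, `solve_field()`).
   The quasi-static potential problem ∇·(σ∇φ) = 0 is discretized on a
   regular voxel grid with a 7-point finite-difference stencil and
   harmonic face averaging of the conductivity σ (exact current
   continuity across the tumor/background jump), Dirichlet potentials
   ±V/2 on the two rasterized needle electrodes, insulating outer
   boundary, and solved by SSOR-preconditioned conjugate gradients. The
   midpoint field is validated against the closed-form two-wire solution
   E = 2V / (d·ln((d−a)/a)).

2. **Lethal-threshold calibration** (`invert_lesion()`,
   `estimate_threshold()`). Lesion extents measured in cell-laden
   hydrogel phantoms are inverted against the solved field: the field
   magnitude at the observed live/dead boundary *is* the lethal
   threshold. Replicates aggregate to the conventional
   "mean ± SD [min to max] V/cm" summary.

3. **Monte-Carlo dose planning** (`sample_scenarios()`, `run_plan()`,
   `select_dose()`). Tumor diameter (4–8 mm), tissue conductivities and
   the threshold (truncated-normal around the calibrated estimate) are
   randomized; per scenario the electrode spacing is 1 mm below the
   tumor diameter and tumor coverage — the fraction of tumor voxels with
   |E| ≥ threshold — is evaluated across candidate voltage-to-distance
   ratios (V/cm). The selected dose is the smallest ratio that fully
   ablates every scenario. `plan_sensitivity()` tabulates how that
   selection moves under the non-measured modeling choices.

4. **Spheroid fluorescence quantification** (`segment_mcts()`,
   `frame_metrics()`, `normalize_track()`, `xtt_normalize()`).
   Otsu-based segmentation of eGFP tumor spheroids, background-subtracted
   green (viability) and deep-red (CAR T-cell infiltration) intensities,
   baseline-normalized longitudinal tracks, and XTT reference-wavelength
   correction (A475 − A660).

5. **In-vivo metrics and survival** (`tumor_volume()`,
   `classify_response()`, `km_estimate()`, `logrank_pairwise()`).
   Caliper volume V = 0.5·L·W², treatment (>100 mm³) and humane-endpoint
   (12 mm) triggers, eradication/recurrence classification, Kaplan–Meier
   curves and pairwise log-rank tests with Bonferroni correction.

6. **Synthetic-data generators** (`gen_hydrogel_lesions()`,
   `gen_spheroid_timelapse()`, `gen_invivo_cohort()`,
   `dose_response_model()`). Seeded, pure-function emulators of each
   input: hydrogel lesions consistent with a ground-truth threshold plus
   measurement noise, two-channel spheroid time-lapses following a
   logistic field→viability model (anchored to ≈95% / 34% / 3% viability
   at 0 / 1,000 / 2,000 V/cm) with post-IRE swelling, sub-lethal
   rebound and CAR-T outside-in erosion, and four-arm mouse cohorts with
   post-IRE eradication, partial recurrence and combination-arm cure.

## Worked example

```r
library(irecar)

## 1. calibrate the lethal threshold from (here: synthetic) hydrogel lesions
cfg <- hydrogel_config(resolution = 0.2)
fm  <- solve_hydrogel_field(cfg)
lesions <- gen_hydrogel_lesions(500, config = cfg, noise_cv = 0.05, n = 5,
                                seed = 42, field = fm)
estimate_threshold(lesions, fm)
#> Lethal electric-field threshold: 470 ± 52 [404 to 548] V/cm (n = 5)
```

Five lesion extents carrying 5% measurement noise around a 500 V/cm
ground truth calibrate back to 470 ± 52 V/cm — the truth is inside one
SD, and the [min to max] range brackets it.

```r
## 2. Monte-Carlo dose planning with a published threshold distribution
pan02 <- threshold_estimate(525, 77, 442, 613, n = 5)
scenarios <- sample_scenarios(30, pan02, seed = 1)
plan <- run_plan(scenarios, resolution = 0.5)  # 0.25 mm for the full run
plan
#> Coverage plan: 30 scenarios x 5 candidate ratios
#>   ratio   mean     sd  n
#> 1  1000 0.7120 0.0999 30
#> 2  1500 0.9502 0.0416 30
#> 3  2000 0.9974 0.0050 30
#> 4  2500 1.0000 0.0000 30
#> 5  3000 1.0000 0.0000 30
select_dose(plan)
#> Selected voltage-to-distance ratio: 2500 V/cm
#>   candidates: 1000, 1500, 2000, 2500, 3000 V/cm
#>   per-scenario applied voltage: 763 to 1742 V
```

Mean coverage rises with the applied ratio; 2,000 V/cm still leaves a
sliver of some tumors under-treated, and 2,500 V/cm is the smallest
candidate at which *every* randomized scenario reaches complete
coverage — the planned dose.

```r
## 3. quantify a synthetic spheroid time-lapse (1,000 V/cm, no CAR-T)
track <- track_frames(gen_spheroid_timelapse(field = 1000, seed = 7))
track[, c("timepoint_h", "normalized_green", "normalized_area")]
#>   timepoint_h normalized_green normalized_area
#> 1           0             1.00            1.00
#> 2           3             0.40            1.10
#> 3          24             0.58            1.10
#> 4          48             0.68            1.10
#> 5          72             0.72            1.10
```

The normalized green (viability) signal collapses to 0.40 at 3 h, then
rebounds to 0.72 by 72 h — the incomplete-ablation signature of a
sub-lethal field — while the spheroid swells ~10% after treatment.

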