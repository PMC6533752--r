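# fibergrade

Quantifies fibrillar collagen in second harmonic generation (SHG) images of
tissue-microarray (TMA) cores and compares tumor grades on two stromal
features — collagen **density** (fibers per region of interest) and
collagen **alignment** (the mean resultant vector length of fiber
orientations) — using a linear mixed-effects model with per-patient random
intercepts. It is aimed at quantitative-pathology work where nuclear-grade
assessment is unreliable from small biopsies and stromal collagen
organization is a candidate adjunct biomarker.

The package contains the full measurement chain plus a synthetic-data
module, so every stage is testable without any external image download:

* `synthetic_spec()` / `generate_cohort()` — SHG-like fibrous core images
  (Gaussian-profile fibers, PSF, Poisson + read noise) with paired
  pseudo-H&E renderings and exact ground-truth fiber tables;
* `segment_he_kmeans()` / `register_intensity()` / `register_landmarks()` —
  H&E-to-SHG registration by color segmentation and multi-resolution
  intensity matching, with a landmark least-squares fallback;
* `extract_fibers()` — a FIRE-style individual-fiber extractor: band-pass
  preprocessing, guarded Otsu binarization, distance-transform ridge
  tracing; fibers strictly longer than 5.301 um (30 px at 0.1767 um/px)
  count as valid;
* `alignment_coefficient()` — the axial (doubled-angle) mean resultant
  length, reported only for ROIs with at least 20 valid fibers;
* `fit_random_intercept_model()` / `compare_grades()` — REML mixed model
  `y_ij = b0 + b1*g_i + b_i + e_ij`, `b_i ~ N(0, s_b^2)`, two-sided Wald
  test of the grade contrast;
* `run_pipeline()` — exclusion of no-signal cores, registration, ROI
  mapping, extraction, metrics, models, and all output tables in one call.

## The statistics in brief

For fiber orientations `theta_1..theta_n` (axial, i.e. defined modulo
180°), the alignment coefficient is

    R = (1/n) * sqrt( (sum cos 2*theta_i)^2 + (sum sin 2*theta_i)^2 )

with `R = 1` for perfectly aligned fibers and `R = 0` for a balanced
orthogonal mesh. Orientations sampled from the doubled-angle von Mises
distribution with concentration `kappa` have population resultant
`I1(kappa)/I0(kappa)` (`vonmises_resultant()`), which serves as the
closed-form oracle in the tests.

Each collagen feature is compared between grades with a random-intercept
model fit by REML; the grade contrast is tested two-sided with
between-within degrees of freedom (`n_patients - 2`).

## Worked example

Generate a small two-group cohort (grade-4-like group with higher fiber
density and orientation concentration), run the pipeline, and compare
grades:

```r
library(fibergrade)

gen   <- generate_cohort(paper_like_cohort_spec(seed = 20190523),
                         "scratch/cohorts/grade_contrast")
cores <- read_manifest(gen$manifest)
out   <- run_pipeline(cores, pipeline_config(), register = TRUE)

print(out$report$models$density[c("beta1", "ci95", "p_value")])
print(out$report$models$alignment[c("beta1", "ci95", "p_value")])
```

Running `analysis/01_generate_cohorts.R` followed by
`analysis/03_pipeline_and_grades.R` performs exactly this and prints:

```
density: grade-4 minus grade-1 effect = 11.667 (95% CI 9.315 to 14.019), p = 9.5e-12
  random-intercept SD = 2.958, residual SD = 3.149, n = 108 ROIs / 36 patients
alignment: grade-4 minus grade-1 effect = 0.097 (95% CI 0.045 to 0.149), p = 0.00062
  random-intercept SD = 0.070, residual SD = 0.054, n = 108 ROIs / 36 patients
```

Read: grade-4-like cores carry ~12 more extracted fibers per ROI and an
alignment coefficient higher by ~0.10, both contrasts positive and
significant, with the random-intercept SD quantifying the between-patient
variation that repeated ROIs of one core share. (The planted ground-truth
contrasts are a ~1.8-fold density ratio and a population alignment
difference of 0.096.)

The numbered scripts under `analysis/` are thin drivers over the package:
`01` generates the synthetic cohorts, `02` tabulates the cohort
bookkeeping after no-signal exclusion, `03` runs the measurement pipeline
and grade models, `04` runs the Monte-Carlo calibration of the mixed
model. Outputs land under `results/`; generated images under
`scratch/` (not part of the repository).

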