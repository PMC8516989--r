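# infantqmri

Quantitative MRI relaxometry and longitudinal trajectory modelling of
infant cortical microstructure, in R.

In the first six months of life the cortex myelinates quickly and
unevenly. Because the longitudinal relaxation time T1 falls as myelin
accumulates — and its reciprocal, the relaxation rate R1 = 1/T1, rises
approximately linearly with myelin fraction — repeated quantitative T1
mapping of the same infants turns cortical maturation into a measurable
growth curve per cortical area. `infantqmri` is for researchers running
such longitudinal infant qMRI studies (and for anyone who wants to
validate the statistical machinery behind one). It provides:

* **T1/R1 mapping** — voxelwise fits of the inversion-recovery signal
  model S(t) = a(1 − b·e^(−t/T1)), fitted as |S(t)| to magnitude images
  by multistart Levenberg–Marquardt; emits T1, R1, R² and
  inversion-coefficient maps (NIfTI in/out, TI schedules in JSON
  sidecars).
* **Growth trajectories** — per-area linear mixed models
  `value ~ age_days + (1 | infant)` whose intercept is the estimated
  value at birth and slope the change per day; random-slope
  alternatives, ML likelihood-ratio model comparison, stream-level
  models with area/hemisphere/stream factors, and Bonferroni adjustment
  by pairwise comparison counts (4 areas → 6, 9 → 36, 8 → 28).
* **A myelin model** — the linear R1–myelin relation and the induced
  asymmetry of T1 changes that motivates comparing growth rates in R1.
* **A gene screen** — postnatal-vs-prenatal log2 fold changes
  (difference of group means of log2 RPKM), per-gene t-tests, selection
  at FC > 4 and a Bonferroni-corrected p threshold, descending-FC
  ranking and export for enrichment services.
* **Overlap QA** — Dice coefficients (2|A∩B|/(|A|+|B|)) between ROI
  delineations, singly or in batches.
* **Synthetic data with ground truth** — Rician IR voxels, a
  13-infant/3-timepoint longitudinal cohort (10 per timepoint, 7
  complete), expression matrices with planted differential expression
  and mask pairs with exact overlap, so every estimator is testable by
  parameter recovery without any data download.

## Worked example

Simulate one noisy inversion-recovery voxel (SNR 50) on the default
20-TI schedule and fit it:

```r
library(infantqmri)
sch <- build_default_schedule()             # 50, 200, ..., 2900 ms
sim <- simulate_ir_voxels(ir_simulation_spec(
  a = 1000, t1_ms = 2000, noise_sigma = 20, n_voxels = 1, seed = 42))
fit_t1_voxel(sim$signals[1, ], sch)
#> IR fit: a = 903.1, b = 2.1057, T1 = 1830.16 ms, R^2 = 0.99074
```

The fit recovers T1 ≈ 1830 ms against a true 2000 ms — an 8.5% error
typical of single-voxel estimation at this noise level (the median
error across many voxels is ≈4%; ROI averaging is what makes the area
trajectories precise).

Simulate a study-sized cohort whose cortical T1 starts at 2.0 s and
shrinks by 1.5 ms/day, then estimate the growth curve:

```r
cohort <- simulate_cohort(cohort_simulation_spec(
  beta0 = 2.0, beta1 = -0.0015, tau = 0.05, sigma = 0.03, seed = 1))
fit_lmm(cohort$table, lmm_spec("t1_s"))
#> linear mixed model (REML), 60 obs, logLik 97.598
#>          term  estimate        se      t df         p
#> 1 (Intercept)  2.006769 1.392e-02 144.21 58 7.985e-76
#> 2    age_days -0.001439 6.582e-05 -21.86 58 1.086e-29
```

The intercept (2.007 ± 0.014 s) is the estimated T1 at birth and the
slope (−1.44 ± 0.07 ms/day) the daily decrease, both close to the
generating truth of 2.0 s and −1.5 ms/day.

Overlap QA on a constructed mask pair:

```r
m <- simulate_mask_pair(3, 5, 2, seed = 1)
dice(m$a, m$b)
#> [1] 0.5
```

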