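# musclefi

Quantification of lumbar muscle composition from axial MRI slices, and the
sex-stratified cohort statistics built on it.

On T2-weighted axial images, intramuscular fat is bright and lean muscle
dark. Given a segmented region of interest for a muscle compartment — the
psoas and the posterior paraspinal muscles (PPM: erector spinae +
multifidus) at the L4 level — the package classifies each pixel as fat or
muscle and reports the quantities used in spine research to grade muscle
quality:

- **CSA** — cross-sectional area of the compartment (cm²), with
  CSA = fCSA + FAT by construction;
- **fCSA** — functional (lean) area;
- **FAT** — fat area;
- **FI** — fat infiltration, FI = (FAT / CSA) · 100 (%), the surrogate for
  muscle degeneration (higher = weaker).

Classification couples an exact Otsu threshold (maximizing the between-class
variance w₁w₂(m₁−m₂)² over all splits of the ROI intensities) with an
iterative multiplicative quadratic bias-field correction
S(x,y) = c₀₀ + c₁₀x + c₀₁y + c₂₀x² + c₁₁xy + c₀₂y², fitted to the
muscle-class pixels and divided out until the fat/muscle split stabilizes.
Side areas are summed (FI recomputed area-weighted), areas are normalized by
height² (cm²/m²), and lumbar lordosis is available as the Cobb angle between
the L1 and S1 superior endplate lines.

Because manual segmentations and patient tables are rarely shareable, the
package also ships two synthetic-data generators that make every stage
testable against known truth:

- a **phantom generator** (elliptical muscle regions, two-valued clean
  intensities, imposed quadratic shading, Gaussian noise, exact fat-pixel
  ground truth), and
- a **cohort generator** calibrated to a published degenerative-spine
  surgical cohort (n = 190, 57.9% female): per-sex demographics, logit-normal
  FI_PPM matched to the <50%/≥50% group structure, FI_Psoas drawn from the
  published regression model with its coefficients as generating values, and
  lordosis by FI group.

The statistics stage reproduces the corresponding analysis on any cohort
table: Kjaer FI grouping (<10 / 10–50 / ≥50%), Shapiro–Wilk-gated t vs
Mann–Whitney group comparisons, sex-stratified Spearman matrices, and an OLS
regression report with b, 95% CI, SE, standardized Beta, t, p, VIF,
corrected R² and the Durbin–Watson statistic. No multiple-testing adjustment
is applied anywhere; p-values are raw.

## Worked example

Measure a phantom with known 40% fat in one region:

```r
library(musclefi)

ph <- generate_phantom(phantom_spec(true_fat_fraction = c(0.4, 0.3, 0.1, 0.05),
                                    seed = 3))
measure_muscle(ph$image, ph$masks, label = 1L)
#> PPM (left): CSA 8.770 cm^2, fCSA 5.260, FAT 3.510, FI 40.0% (877 px)
```

The measured FI equals the planted truth exactly on a clean image; under a
bias field with max/min ratio 1.5 and overlapping class ranges the corrected
measurement stays exact while skipping the correction
(`measure_config(bias_correction = FALSE)`) misses by ~3.5 FI points on
average.

Simulate the default cohort and run the analysis stage:

```r
tab <- generate_cohort(calibrate_defaults(), seed = 7)
rep <- analyze_cohort(tab)
rep$correlations$female$rho["FI", "FI"]
#> [1] -0.4314
print(rep$regression)
#> Multiple linear regression, n = 190: R^2 = 0.175, corrected R^2 = 0.153, ...
#>         term      b ci_low ci_high    se   beta      t     p   vif
#>       FI_PPM -0.216 -0.292  -0.140 0.038 -0.456 -5.618 0.000 1.470
#>       ...
```

The negative FI_PPM row is the package's core finding reproduced in
synthesis: cohorts generated under the default calibration show the inverse
association between paraspinal and psoas fat infiltration in both sexes.

The numbered drivers under `analysis/` run the full study as a pipeline —
`01_phantom_validation.R` (estimator accuracy and bias-correction benefit),
`02_simulate_cohort.R`, `03_cohort_analysis.R` (all five report tables under
`results/report/`), `04_recovery_simulations.R` (200-replicate parameter
recovery) — each writing its tables under `results/`.

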