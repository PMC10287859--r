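# perirad

Peritumoral DCE-MRI radiomics with PLS classification, for predicting the
high recurrence-risk class (Oncotype DX recurrence score, RS > 25) in
ER+/HER2− breast cancer from dynamic contrast-enhanced T1-weighted MRI.

Patient imaging of this kind is rarely shareable, so the package ships a
synthetic 3D phantom cohort generator with the statistical structure the
analysis assumes (class-linked lesion texture and peritumoral rim
enhancement, two noisy readers, two DCE phases). Every stage of the pipeline
is exercised and tested end-to-end on phantoms; real cohorts are consumed as
NIfTI volumes + reader masks + a labels CSV.

## The method

1. **Compartments.** From each reader's tumor mask T, the peritumoral
   compartment TST ("tissue surrounding tumor") is built by physical-unit
   morphology: `TST = dilate(T, 2 mm) \ erode(T, 2 mm)`, a 4-mm ring
   straddling the tumor boundary.
2. **Features.** Volumes and masks are resampled to 1, 2 and 3 mm isotropic
   grids. Per masked image, ten filters (original, 8-band wavelet, LoG,
   square, square root, logarithm, exponential, gradient, LBP2D, LBP3D) and
   seven feature classes (first-order, shape, GLCM, GLRLM, NGTDM, GLDM,
   GLSZM) give 1409 features — 93 intensity/texture features × 15
   feature-yielding derived images + 14 shape descriptors. Across 2 phases ×
   2 compartments × 3 resolutions × 2 readers a subject has 33,816 values.
3. **Repeatability.** Only features with inter-reader product-moment
   correlation r > 0.95 across subjects are kept; the two readers' values are
   averaged into a consensus table.
4. **Model.** PLS1 regression of the binary label (1 = RS > 25) on z-scored
   features. The single hyperparameter, the number of latent components k, is
   tuned by inner leave-one-out AUC within a leave-one-out *nested*
   cross-validation; each subject's risk score comes from a model never
   trained on it. The per-feature β-weights rank the features; the top 5% are
   profiled by phase, compartment, resolution and feature class.
5. **Significance.** Out-of-fold scores → ROC AUC; labels are shuffled
   (default 10⁵ draws) against the fixed scores to build a permutation null,
   giving z = (AUC − mean₀)/sd₀ and an empirical p-value. Seven
   phase/compartment combinations (a)–(g) are analysed independently.

## Worked example

```r
library(perirad)

cfg <- run_config(
  cohort = cohort_config(n_subjects = 16, prevalence = 0.25,
                         grid_shape = c(16, 16, 16), spacing_mm = c(2, 2, 2),
                         lesion_radius_mm = c(5, 8), seed = 21),
  extraction = extraction_config(filters = "original",
                                 feature_classes = "firstorder",
                                 resolutions_mm = 2),
  combination = "a", k_grid = 1:2, n_perm = 500, perm_seed = 3)
report <- run_pipeline(cfg)
print(report)
#> <run_report> 16 subjects ( 4 positive ), 72 feature columns
#>   (a) repeatable=70 AUC=1.000 z=3.23 p_emp=0.001996 *
```

16 phantom subjects (4 high-risk), 72 first-order feature columns (2 phases ×
2 compartments × 18 features), of which 70 pass the inter-reader filter at
this scale. The out-of-training-sample AUC of 1.0 sits 3.23 null standard
deviations above the permutation-null mean, empirical p ≈ 0.002: the class
effect built into the phantoms is recovered (at these default effect sizes
and this small n, separation is complete). With zero generator effect sizes
the same call reports AUC near 0.5 and a non-significant p.

The same pipeline runs from the command line in stages
(`simulate`, `extract`, `select`, `ncv`, `report`, `all`):

```sh
Rscript inst/cli/perirad.R all --config config.yaml
Rscript inst/cli/perirad.R ncv --config config.yaml --combination peak/TST
```

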