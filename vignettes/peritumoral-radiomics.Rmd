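---
title: "Peritumoral DCE-MRI radiomics with PLS: models, phantoms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peritumoral DCE-MRI radiomics with PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(perirad)
```

## The problem and the model

Breast-cancer patients with ER+/HER2− tumors are stratified for adjuvant
chemotherapy by the Oncotype DX recurrence score (RS, 0–100); RS > 25 marks
the high-risk class. This package implements an imaging surrogate: predict
the binary risk class from radiomics features of dynamic contrast-enhanced
(DCE) T1-weighted MRI, using both the tumor (T) and the 4-mm peritumoral ring
(TST) on the first ("early") and second ("peak") post-contrast phases.

The classifier is PLS1 regression: with z-scored features $X$ and labels
$y \in \{0,1\}$, latent components $t_a = X w_a$ are extracted sequentially to
maximize covariance with $y$, and predictions are linear,
$\hat y = b_0 + X\beta$. PLS is appropriate here because the feature battery
is far wider than the cohort and strongly collinear (the package reports the
mean absolute pairwise correlation as a collinearity diagnostic;
`mean_abs_correlation()`). The only hyperparameter is the number of
components $k$, tuned in the inner loop of a leave-one-out nested
cross-validation; each subject's score therefore comes from a model that
never saw that subject, including its standardization parameters (see
"Numerical choices"). Coding $y = 1$ for high risk makes a positive
$\beta_j$ read as "higher feature value, higher predicted risk".

Statistical significance of the out-of-fold AUC is assessed by permutation:
labels are shuffled against the fixed scores, the AUC null distribution is
recorded, and the observed AUC is expressed both as
$z = (\mathrm{AUC}-\mu_0)/\sigma_0$ with a one-sided upper-tail normal
p-value and as an empirical p-value
$(1 + \#\{\mathrm{null} \ge \mathrm{AUC}\})/(1 + n_\mathrm{perm})$. Both are
reported because the normal approximation is only as good as the null's
tails.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `dilate_mm`, `erode_mm` | 2, 2 | TST ring construction; total thickness 4 mm in physical units, independent of voxel size |
| `resolutions_mm` | 1, 2, 3 | isotropic resampling targets before extraction |
| `bin_width` | 25 | fixed-width gray-level discretization, edges anchored at the in-mask minimum (so texture features are intensity-shift invariant) |
| `repeatability_threshold` | 0.95 | strict `r > 0.95` inter-reader filter |
| `k_grid` | `1:min(30, n-2, p)` | candidate PLS components; must contain the optimum, hence the generous ceiling |
| `n_perm` | 1e5 | permutation draws (1e6 is configurable; 1e5 keeps routine runs fast with identical inference at the reported p-values) |
| `top_fraction` | 0.05 | share of features profiled by β-weight magnitude |

## The feature battery and the pinned 1409

The per-masked-image count decomposes as
$1409 = 15 \times 93 + 14$: 93 intensity features (18 first-order + 24 GLCM +
16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM) on each of 15 feature-yielding
derived images (original, 8 undecimated Haar wavelet sub-bands, square,
square root, logarithm, exponential, gradient magnitude, slice-wise LBP2D),
plus 14 shape descriptors computed once on the original image. Two filters in
the configured set of ten contribute no features by default:
Laplacian-of-Gaussian ships with an empty scale list (supply `log_sigma_mm`
to enable it, which changes the total), and LBP3D is a placeholder only. This
is the only decomposition consistent with the pinned total, and the package
treats that total as a contract: `extract_features()` under the default
configuration always returns exactly 1409 values.

Feature definitions follow IBSI-style conventions but are computed natively;
bit-for-bit parity with any particular extractor is a non-goal. Analytic
phantoms pin correctness instead: constant regions (zero variance/entropy/
contrast), a checkerboard with hand-enumerated co-occurrences, a striped
strip with known runs and zones, and a solid block with an exactly known
dependence profile. Two shape descriptors are voxel-based approximations:
`MeshVolume` equals the voxel volume and `SurfaceArea` counts exposed voxel
faces (which overestimates smooth surfaces, biasing `Sphericity` low). These
remain useful as relative features but should not be compared across
packages in absolute terms.

Degenerate feature values (e.g. a single gray level after discretization,
which is the norm for the LBP2D image under a 25-unit bin width) are NaN by
convention and the affected columns are dropped cohort-wide, symmetrically
across readers, before modeling.

## What the phantom generator emulates — and what it does not

`generate_cohort()` produces a stated world: ellipsoidal lesions
(semi-axes drawn from `lesion_radius_mm`) on a configurable grid (default
64³ at 1×1×2 mm, anisotropic on purpose so resampling is always exercised),
background 100, lesion enhancement +150 on "early" and ×`enhancement_ratio`
(default 1.6) on "peak", additive Gaussian noise (`noise_sd` = 10), and two
class effects:

- **texture**: a smoothed Gaussian random field inside the lesion whose
  amplitude (40) and correlation length (1.5 mm) are both multiplied by
  `1 + 0.25 * texture_effect` for positives — chosen because GLCM-type
  features respond to both amplitude and correlation length;
- **rim**: voxels in a 4-mm shell outside the true boundary are multiplied by
  `1 + 0.08 * rim_effect` for positives, mirroring the peritumoral
  enhancement the TST compartment is designed to capture.

Defaults `texture_effect = rim_effect = 1` give a moderate, detectable
signal; `0` gives exact class exchangeability (the generator draws the same
random sequence regardless of label, so null cohorts are null by
construction, not approximately). Reader variability is simulated by eight
random boundary patches per mask, each a spherical dilation or erosion of
radius `reader_perturb_mm` (default 1 mm). The paper-world magnitude of
inter-reader disagreement is unknown; the default was chosen so that a
nontrivial fraction of features fails the r > 0.95 filter (about 40% fail
in a 32³ test cohort), which is the property the filter needs in order to be
testable at all.

Not emulated: MR physics (bias fields, Rician noise), pharmacokinetic
enhancement curves, multifocal disease, irregular lesion shapes, breast
anatomy around the ring. A green pipeline test therefore establishes that
the *procedure* recovers a class signal of the stated form and rejects
properly without one — not that the effect sizes resemble clinical ones.

## Numerical choices

- **Standardization**: z-scoring uses the sample (n−1) standard deviation.
  By default it is refit inside every outer training fold, which is stricter
  than z-scoring once on the full cohort; the original analysis' global
  convention is available via `global_zscore = TRUE`. Zero-variance columns
  are dropped with a warning, never imputed.
- **Repeatability before CV**: the r > 0.95 filter runs once on the full
  cohort, as the source analysis did. This leaks a little information across
  folds (the filter saw every subject); we keep it for fidelity and note
  that the permutation test of the final AUC is unaffected under the null
  because shuffled labels never enter the filter.
- **PLS algorithm**: NIPALS with the beta-path recursion (P'W is unit upper
  triangular, so coefficients for all k come from one pass). At
  k = rank(X) with n > p the coefficients equal ordinary least squares — a
  tested identity that makes NIPALS/SIMPLS interchangeable here.
- **Inner criterion**: inner leave-one-out AUC, ties broken toward the
  smallest k (parsimony). The source does not name its inner metric; this
  choice is recorded as ours.
- **AUC**: midrank Mann–Whitney, ties counted 1/2.
- **Permutation null sd**: n−1 denominator (documented because z-values on
  tiny nulls depend on it).
- **Permutation scope**: labels are shuffled against fixed out-of-fold
  scores; the nested CV is not re-run per permutation. Under the null the
  out-of-fold scores of a leave-one-out pipeline are slightly
  *anti*-correlated with the labels (each held-out subject pulls its class
  mean out of the training set), so the observed null AUC tends to sit below
  0.5 (mean ≈ 0.46 in the desk-scale null simulation), while the adaptive
  inner-k selection widens it; the net measured type-I rate over 200 null
  cohorts is ≈ 4.5% at the nominal 5%. This mild conservatism is a property
  of the procedure itself, visible in the type-I acceptance simulation, not
  an implementation artifact.
- **Tie-break in the top-5% ranking**: boundary ties resolved by
  lexicographic key order, making the reported feature list deterministic.
- **Degenerate inputs**: empty masks, single-class folds, empty
  post-resampling masks, and empty repeatable-feature sets all raise typed
  errors naming the subject/stage rather than propagating NaNs.

## Design choices where the design was open

- **Which reader feeds the model** is unstated in the source; the consensus
  table averages the two readers (configurable to reader 1 or 2 for
  sensitivity analyses).
- **β-weights for the profile** come from a final all-subject fit at the
  modal inner-selected k, rather than averaging fold-wise fits; the modal k
  is reported alongside.
- **Stage artifacts** are plain CSV/JSON files keyed by name in `out_dir`;
  a content-hash cache was considered and rejected because synthetic runs
  are seconds long and hashing would add opacity for no saved time.
- **The ring is not clipped** to any anatomy (the source's manual
  adjustment step); the QC report (`tst_qc()`) flags rings touching the
  image boundary instead.
- **LBP3D** is accepted in configurations but not implemented; enabling it
  explicitly errors. This matches the pinned feature count, which admits no
  LBP3D contribution.

## Limitations

Shape descriptors are voxel-based approximations (above). The NIfTI reader
handles axis-aligned single-file NIfTI-1 only and ignores orientation
matrices. The phantom world is deliberately simple; in particular the
texture field is stationary inside the lesion, so features sensitive to
radial gradients are only exercised through the rim effect. Nothing in the
test suite certifies clinical performance: the headline numbers of any real
cohort depend on data this package cannot see.
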