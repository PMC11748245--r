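---
title: "Methods: encrypted multi-region radiomics with encrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encrypted multi-region radiomics with encrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Response to EGFR-TKI and ICI therapy in NSCLC correlates with molecular
markers (EGFR mutation subtypes 19Del/L858R/T790M, PD-1/PD-L1 expression)
that require invasive testing. CT radiomics can approximate these labels
noninvasively, but two issues undermine routine use: CT volumes are
identifiable patient data that must be protected in transit, and features
from a single tumor region ignore the peritumoral microenvironment.
`encrad` implements an auditable pipeline that encrypts regions of interest
losslessly before they leave a trusted environment and fuses intratumoral
(2D and 3D) with peritumoral and clinical information.

This vignette documents the modeling choices, the tunable parameters, the
numerical conventions, and what the synthetic validation does — and does
not — establish.

# Regions of interest

From a 3D binary tumor mask on the CT grid the package derives:

* **2D region** — the axial slice with the largest tumor area (ties break
  to the lowest slice index; deterministic). Resampled to 0.8 mm × 0.8 mm
  in-plane.
* **3D region** — the full tumor, resampled to 1.0 mm isotropic.
* **Peritumoral region** — all background voxels whose center lies within
  3 mm (Euclidean distance in physical mm, honoring anisotropic spacing)
  of any tumor voxel center; clipped at image borders; resampled to 1.0 mm
  isotropic.

Whether the peritumoral region should be a planar ring around the selected
slice or a 3D shell is genuinely ambiguous in the field; the 3D shell is
the default here (consistent with the 1.0 mm isotropic spacing it
receives), and `peritumoral_mode = "ring2d"` provides the planar variant.
The shell is deliberately *not* masked to lung parenchyma: that keeps the
definition purely geometric and reproducible, at the cost of occasionally
including chest-wall-like voxels for pleural tumors. Intensity
interpolation is trilinear; masks use nearest neighbor; the resampled grid
has `round(dim * spacing / target)` voxels per axis, preserving physical
extent to within one voxel. All indices are 1-based and axial slices run
along the third array axis.

# Encryption and audits

Regions are serialized canonically — little-endian, column-major, signed
16-bit integers for integral HU volumes (CT convention), float64 otherwise
— padded with PKCS#7 and encrypted with AES-256-CBC. The IV is random per
image (from `openssl` when present, otherwise R's RNG, which is
reproducible but not cryptographically unpredictable — production
deployments should supply externally generated keys and IVs) and is stored
in the container; CBC confidentiality does not require a secret IV. Keys
never appear in any output. Decryption validates padding and payload size,
so a wrong key fails loudly instead of yielding silent garbage; the
decrypted array lives only in memory.

Two audits mirror standard image-cipher practice:

* **Fidelity** — SSIM between original and decrypted images, computed with
  the conventional 11-tap Gaussian window (sd 1.5, renormalized at edges)
  and constants K = (0.01, 0.03) on the joint dynamic range. The AES round
  trip is bit-exact, so SSIM is exactly 1.
* **Security** — Pearson correlation of randomly sampled adjacent pixel
  pairs in the horizontal, vertical and diagonal directions, for the
  plaintext slice versus the ciphertext bytes rendered as an image.
  Natural CT correlates strongly (> 0.9 on smooth structures); a sound
  cipher's output is indistinguishable from noise (|r| < 0.05 at 5000
  pairs). A zero-variance sample is flagged `defined = FALSE` rather than
  propagating `NaN`.

The AES core is implemented in C++ with its S-box and round tables derived
from GF(2^8) arithmetic at load time; the test suite pins it against
published known-answer vectors and an independent reference
implementation.

# Feature extraction

Per region, from the original image: 14 shape, 19 first-order, 24 GLCM,
16 GLRLM, 16 GLSZM, 5 NGTDM and 14 GLDM features (108 values). With the
wavelet option, the intensity-based families (not shape) are recomputed on
each sub-band of a one-level stationary (undecimated) coif1
decomposition — 8 sub-bands in 3D, 4 for the planar region — giving
108 + 8×94 = 860 features for a 3D region. The stationary transform keeps
sub-bands on the input grid so the mask applies unchanged; with the
orthonormal coif1 filters and periodic boundaries, sub-band energies sum
to 2^d times the input energy, which the tests verify (Parseval).

Key conventions, each configurable where meaningful:

* **Discretization**: fixed bin width of 25 HU (the de facto CT radiomics
  default), `level = floor((x − min)/w) + 1`; a fixed-bin-count mode is
  available and is the one that makes level-based features invariant to
  global intensity shifts.
* **GLCM/GLRLM aggregation**: symmetric matrices for all 13 unique unit
  direction vectors (4 in-plane for the 2D region), features computed per
  offset and averaged; offsets yielding no voxel pairs are excluded from
  the average.
* **Neighborhoods**: 26-connectivity for GLSZM zones and NGTDM/GLDM
  neighborhoods (8 in-plane); GLDM dependence tolerance alpha = 0.
* **Entropies** are in bits and computed over strictly positive
  probabilities. Degenerate cases have stated conventions instead of NaN:
  constant regions get skewness/kurtosis 0, uniformity 1, NGTDM coarseness
  capped at 1e6, GLCM correlation 1.
* **Shape**: surface area and mesh volume come from a watertight
  marching-tetrahedra iso-surface (level 0.5) of a lightly smoothed
  indicator field (Gaussian sd 0.9 voxels, mask voxels floored just above
  the iso level so thin structures never vanish). Smoothing the indicator
  before meshing removes the staircase bias of meshing raw binary masks —
  on a digital ball of 10 mm radius the mesh volume and sphericity land
  within a few percent of the analytic values, which the suite asserts.
  Axis lengths use the principal-component convention 4·sqrt(eigenvalue);
  maximum diameters are the largest pairwise distances between
  border-voxel centers (overall and per orthogonal plane). The 2D region
  is treated as a slab of one-voxel thickness so the same 14 definitions
  apply — the documented 2D "name mapping" is the identity.

The per-family cardinalities (14/19/24/16/16/5/14) are contractual and
asserted by tests. A note on totals: summing the families gives 108
original-image features and 860 with eight wavelet sub-bands; published
feature totals in this literature sometimes disagree with their own
per-family counts, so the per-family counts are treated as authoritative
here.

Texture counting kernels (pair, run, zone, neighborhood enumeration) are
C++ for speed; every feature is verified against brute-force R oracles
written independently (all-pairs enumeration, union-find components,
direct neighborhood averaging) at 1e-10 tolerance on random small masks.

# The RadScore cascade

Fitted strictly on the training split:

1. **Z-score normalization** with training means/SDs; constant features
   are flagged and dropped; test data always use training parameters.
2. **Screening**: two-sided Mann-Whitney U per feature (exact when both
   groups have ≤ 8 observations, otherwise normal approximation with tie
   correction), Benjamini-Hochberg step-up at FDR 5%.
3. **mRMR**: greedy mutual-information-difference ranking (relevance minus
   mean redundancy), with MI on 4-quantile discretized features; k = 30
   retained by default (the paper-scale funnel from hundreds of features
   to a LASSO-sized set; configurable). Quantile discretization makes the
   criterion scale-free and deterministic; ties break on column order.
4. **LASSO**: L1-penalized logistic regression (binary outcomes with a
   misclassification criterion imply classification, so "LASSO
   regression" is interpreted as penalized logistic) over a 50-value
   log-spaced path down to 1e-3 of the data-derived maximal lambda.
   Lambda minimizes the mean 5-fold stratified-CV misclassification
   error; ties pick the larger (sparser) lambda; the final model is refit
   on the full training set. Degenerate single-class folds trigger up to
   three refolds before erroring.

`RadScore = intercept + Σ coef_j · z_j`. Containment (LASSO features ⊆
mRMR set ⊆ FDR survivors) holds by construction and is asserted. When the
screen rejects nothing (as under a true null) the model degenerates to a
constant score, which scores AUC 0.5 under the midrank convention — the
honest null behavior.

# Models and evaluation

Five model families per target label: clinical (covariates chosen by
backward stepwise logistic regression minimizing AIC = 2k − 2 log L),
three regional models (each region's RadScore as sole predictor), and the
combined radiomics-clinical model (AIC-retained covariates plus a RadScore
re-fitted on the pooled three-region feature table — pooling, not
averaging regional scores, lets the cascade trade features across regions).
The classifier registry holds logistic regression, linear and RBF SVM,
random forest, gradient boosting, kNN and naive Bayes; hyperparameters are
chosen by 5-fold cross-validated AUC over small grids, and probabilities
come from each learner's calibrated output (Platt scaling inside the SVM).
Evaluation on the held-out split: AUC with stratified percentile-bootstrap
CIs (B = 1000 by default); accuracy/sensitivity/specificity at the Youden
threshold fixed on training predictions; paired DeLong tests (placement-
value covariance) against the combined model; decision curves with
treat-all/treat-none references on a 0.01–0.60 threshold grid; and
30-repeat 5-fold stratified CV, which by construction places every sample
in a test fold exactly 30 times. No multiplicity adjustment is applied
across target labels, matching per-target reporting practice.

# Stratified biomarker analysis

RadScore groups use tertile boundaries (33.3/66.7 percentiles) estimated
on training scores, with half-open intervals: a score exactly on a
boundary joins the upper group. The literature's wording oscillates
between "quartiles" and "tertiles" for this construction; three groups
are what the stratified analyses display, so tertiles are the default and
a quartile mode (middle two quarters merged) is provided. Group assignment
is invariant under monotone transforms of the score. Per-group positivity
rates keep exact fractions alongside percentages, and Spearman rho between
RadScore and each label uses midrank ties with a t-approximation p-value
(exact enumeration for n ≤ 9), BH-adjusted across the correlation matrix.

# The synthetic cohort generator

`phantom_spec()`/`generate_cohort()` emulate the statistical structure the
analysis needs, not lung anatomy:

* **Geometry**: random ellipsoids (mean radius 5–8 mm by default) centered
  near the middle of a 36×36×30 voxel volume at 1.25 mm isotropic spacing;
  background is lung-like (−780 HU) with Gaussian noise (sd 20 HU).
* **Texture**: inside the tumor (and independently in the 3 mm shell), a
  Gaussian random field — white noise smoothed with a per-patient Gaussian
  kernel (correlation length rho) and scaled to amplitude tau. A label
  effect of `s` SD shifts the population means of both tau and rho by `s`
  between-patient standard deviations for positive patients. Because the
  intratumoral and peritumoral fields have separate parameters, signal can
  be implanted per compartment, which is what lets the tests show the
  combined model beating single-region models.
* **Labels**: prevalences default to EGFR 38.5%, 19Del 19.1%, L858R 14.9%,
  T790M 9.2%, PD-1/PD-L1 47.1%; the EGFR subtypes are drawn hierarchically
  (19Del/L858R mutually exclusive within EGFR+, T790M conditional on
  EGFR+) so marginals and subtype logic are both respected.
* **Clinical covariates** (age, gender, smoking, tumor location, LVI,
  pleural invasion, T stage) are drawn with realistic marginals and are
  independent of the labels unless a per-label `clinical_effect`
  coefficient is set, which tilts age, smoking, LVI, PI and T stage on the
  log-odds scale.
* Intensities are rounded to integer HU and clamped to the 12-bit CT
  range, which also fixes the canonical 16-bit serialization for
  encryption. Cohorts are pure functions of their seed.

Effect sizes are test instruments: no published effect-size estimates
exist for these labels, so the defaults (zero) define the null and the
calibration studies choose explicit shifts.

**What the synthetic validation shows** — that the pipeline is
leakage-free and calibrated (test AUC ≈ 0.5, FDR respected, with no
implanted effect), that it recovers implanted texture signal (median test
AUC > 0.8 at a 1.5 SD shift, n = 300), and that fusing compartments and
clinical data dominates single sources when signal is split across them.
**What it does not show** — performance on real CT: phantoms have no
scanner effects, no anatomy, no segmentation variability, and their
texture model is far simpler than tumor biology. Published AUCs on private
patient cohorts are not reproducible from synthetic data and are not
claimed.

# Problem sizes and numerical notes

The calibration studies run the full pipeline (ROI derivation, AES round
trip, extraction, cascade, evaluation) on cohorts of n = 300 with
original-image features (108 × 3 regions = 324 columns) — the wavelet
option multiplies extraction cost roughly ninefold and adds nothing to
these structural checks, so it stays off there; 20 seeds for the null
study, 10 for each recovery study. The brute-force oracle sweep uses 50
random masks up to 8³ voxels. Bootstrap CIs default to B = 1000 (B = 200
to 500 in the heavier loops). Smoothing kernels are truncated at 3 sd and
renormalized at edges. The mRMR MI cache and GLCM index caches are exact
optimizations with no effect on values.

# Known limitations

* The feature set follows IBSI definitions under one aggregation choice
  per family; it is not a certified IBSI implementation across all
  aggregation variants.
* DCA probabilities for the regional models come from a univariable
  logistic calibration of the RadScore; other calibrations would shift
  net-benefit curves slightly.
* The generator's clinical covariates are mutually independent given the
  labels; real covariates correlate (age with smoking, stage with
  invasion).
* R's RNG-based IV fallback is reproducible, hence unsuitable for
  adversarial settings; supply `openssl` keys/IVs in production.
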