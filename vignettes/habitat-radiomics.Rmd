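---
title: "Habitat radiomics for breast DCE-MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics for breast DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dcehabitat` implements a habitat-based radiomics pipeline for dynamic
contrast-enhanced breast MRI: lesion segmentation on subtraction images,
kinetic partitioning of the lesion into rapid/medium/slow time-to-peak
subregions, extraction of a 488-feature texture bank per region, and binary
classification with fold-wise feature selection and a linear SVM under
leave-one-out cross-validation (LOOCV). This vignette is the package's own
account of the science: the model and its assumptions, the parameters that
matter, what the synthetic phantom does and does not emulate, and the design
choices made where the design was genuinely open.

## 1. The kinetic model and its assumptions

Each pixel's kinetic curve is the relative enhancement in percent,
`E(x,y,t) = (SI(x,y,t) − SI(x,y,t0)) / SI(x,y,t0) × 100` over post-contrast
phases `t = 1..8`, and its time-to-peak is `TTP(x,y) = argmax_t E(x,y,t)`.
Three points deserve attention:

* **Ties break to the earliest phase.** TTP is the time at which peak
  enhancement is *achieved*; the first phase attaining the maximum is the
  natural reading, and it makes the map deterministic on plateau curves.
* **Near-zero baselines are flagged, not divided by.** Pixels with
  `SI(x,y,t0)` below `epsilon_baseline` (default 1 intensity unit) get no
  enhancement value, no TTP, and no habitat label; their count is logged on
  the enhancement object. Air and fat-suppressed background would otherwise
  produce arbitrarily large percentages. How such pixels were handled
  clinically is not documented anywhere we know of; the guard is our
  addition.
* **TTP is invariant to global intensity rescaling** (`SI → a·SI`, `a > 0`),
  because `E` is a ratio. This is asserted as a property test.

The partition rule — TTP in phases 1–4 is rapid, 5–6 medium, 7–8 slow — is
applied inside the lesion mask; rapid, medium and slow are pairwise disjoint
and their union is exactly the set of in-mask pixels with a valid TTP.

## 2. Segmentation

Inside a user-supplied rectangular ROI on a subtraction image, a **spatial
fuzzy C-means** (sFCM) with two clusters separates enhancing lesion from
background; the brighter cluster, hard-assigned, is refined by keeping the
largest 8-connected component, filling interior holes, and one binary opening
with a 3×3 structuring element.

The sFCM variant is the common membership re-weighting formulation: after the
standard FCM membership update, each pixel's membership in cluster *k* is
multiplied by the 3×3 neighbourhood sum of memberships raised to power
`q` (own membership to power `p`; defaults `p = q = 1`), then renormalized.
At `q = 0` it degrades to plain FCM. Hyperparameters nobody publishes were
fixed once: fuzzifier `m = 2`, tolerance `1e-5` on the center displacement,
200 iterations maximum, and deterministic initialization at the 10th/90th
intensity percentiles (no random restarts, so segmentation is a pure
function of its inputs).

Two numerical caveats:

* **Objective monotonicity.** Plain FCM decreases its objective at every
  step and the test suite asserts this. With the spatial term active, the
  tracked objective is not the quantity being minimized and small increases
  (order 1e-3 relative) occur; convergence is therefore judged on center
  displacement. This is a deliberate deviation from asserting strict
  monotonicity in the spatial mode.
* **Degenerate ROIs.** A constant ROI has coincident cluster centers and
  raises an error. An ROI containing only noise splits into two clusters
  about 1.6 noise-SD apart; a genuine enhancing lesion separates by many
  multiples of the within-cluster spread. The guard "center separation ≥ 4
  within-cluster standard deviations" distinguishes the two; the factor 4
  sits between the pure-noise ratio (≈2.7 for a split Gaussian) and the
  weakest lesion we consider segmentable.

A **bypass mode** accepts an externally supplied mask unchanged, so kinetics,
texture and modeling are testable independently of segmentation quality.

## 3. The 488-feature texture bank

* **Histogram (4):** mean, population variance, standardized skewness and
  *excess* kurtosis of raw in-mask intensities (a config flag restores
  Pearson kurtosis). Constant regions get variance 0 and flagged
  skewness/kurtosis.
* **GLCM (380):** 19 Haralick/Soh–Tsatsoulis/Clausi statistics on
  symmetrized, normalized co-occurrence matrices. The published catalogue
  implies 16 directed offsets (distances 1–4 × angles 0/45/90/135°) but
  totals 380 = 19 × 20; the only reading consistent with both is 16 directed
  configurations plus 4 per-distance angular means (`"<STAT> d<d> avg"`),
  and that is what we implement, keeping the directional features
  individually addressable. Direction tokens follow the radiological naming
  convention in which `(0,d)` labels the 90° direction (so `"ACOR (0,1)"`
  is distance 1, vertical); note the token `(d,d)` vs `(-d,-d)` distinction
  in this convention does not survive matrix symmetrization, so we compute
  the four genuinely distinct digital directions and attach the tokens as
  labels. IMC is the first information measure of correlation; logarithms
  are natural; `0·log 0 := 0`; correlation of a degenerate marginal is 0.
* **GRLM (44):** 11 run-length statistics × 4 angles from maximal
  same-level runs along each digital direction, with runs broken at the mask
  boundary. "Fraction of image in runs" is the run count over the pixel
  count. A genuine checkerboard, contrary to folklore, has *long* runs on
  both diagonals (the parity of i+j is constant along them); the test suite
  asserts the hand-derived diagonal run-length distribution.
* **DWT (60):** 4-level periodized 2-D decomposition of the mask-cropped,
  zero-padded bounding box (padded to a multiple of 16) for haar,
  Daubechies-2 and Symlet-4, with the standard orthonormal analysis filters
  hardcoded. Per level: mean absolute coefficient of the horizontal,
  vertical and diagonal detail subbands and the approximation, restricted to
  coefficients over the down-sampled mask, plus a pooled detail scalar
  `D_l`. Four layers × {HH, HV, HD, L} yields only 16 natural scalars
  against a published count of 20 per wavelet; the pooled `D_l` is our
  choice to complete the count, and is recorded as such. The mask pyramid
  uses 2×2 block-any downsampling — exact support tracking for haar, an
  approximation for the longer filters.
* **Quantization:** GLCM/GRLM operate on min–max quantized levels 1..64
  (the common radiomics default; config-exposed). Whether the original
  analysis quantized at all, and at how many levels, is undocumented.

Regions smaller than `min_region_pixels` (default 10) yield fully flagged
(`NA`) vectors rather than errors; the modeling stage drops such rows
listwise. The catalogue — 4 + 380 + 44 + 60 = 488 unique, stably ordered
names — is asserted at extraction time.

## 4. Selection and classification without leakage

All selection happens *inside* each LOOCV loop, on the training rows only —
including the two pre-filters. Applying the variance and correlation filters
once globally would leak held-out distributional information into every
fold; the fold-wise reading is the leakage-free one and is what we
implement. The correlation filter resolves each offending pair by dropping
the later feature in catalogue order (deterministic; the original tie-break
is unpublished).

* **PCA:** components to > 95% cumulative explained variance on z-scored
  training rows; held-out rows are projected with the stored loadings.
  The published methods mention a "wrapper" selector while the results
  report PCA; we implement PCA as the replication set (a greedy
  forward-AUC wrapper exists behind a flag but is not the default path).
* **LASSO:** L1-penalized logistic regression (glmnet), penalty chosen by
  stratified 5-fold inner CV on the training rows. The inner fold
  assignment ranks rows canonically (lexicographic feature order within
  class) before the seeded assignment, which makes LOOCV scores exactly
  invariant to the row order of the input table while remaining
  seed-driven.
* **Stepwise:** bidirectional logistic stepwise with likelihood-ratio
  chi-square entry/removal tests, `p_enter = 0.05`, `p_remove = 0.1`,
  capped at `2 × n_features` iterations. The published description uses
  F-statistic language, which belongs to linear models; the LR chi-square
  is the logistic analogue (a Rao score-test alternative is a config flag).

The classifier is a **linear SVM** (L1-loss dual coordinate descent, C = 1
by default), with decision values mapped to [0, 1] by Platt scaling fitted on
training decisions. Kernel and cost were never published; with ≤ 76 cases
and a fold-wise selected feature set, linear is the defensible default and
an RBF kernel would add two unidentifiable hyperparameters.

**The empty-selection fallback matters.** When a fold selects nothing, the
model must score a constant 0.5. Scoring the training prior instead is
subtly catastrophic under LOOCV: the held-out case's class is always the
underrepresented one in training, so prior-based scores anti-correlate
perfectly with the labels and null-cohort AUCs collapse toward 0 — an
artifact, not a signal. The test suite pins this behaviour.

Even with the fix, null-cohort LOOCV AUCs scatter widely (≈0.32–0.57 across
seeds at n = 60) and sit slightly below 0.5 on average — the well-known
pessimistic bias of LOOCV with internal selection. The acceptance criterion
therefore checks the null AUC against the 95% permutation band of the
realized scores rather than against 0.5 itself.

## 5. The synthetic phantom: what it emulates, and what it does not

The phantom states the world the pipeline is tested in:

| parameter | default | meaning |
|---|---|---|
| `n_cases`, `class_balance` | 76, 42/76 | clinical cohort size and prevalence |
| `image_size` | 128 px | desk-scale stand-in for a 1024×1024 scanner matrix |
| `n_phases`, `phase_interval_s` | 8, 80 s | post-contrast protocol |
| `baseline` | 100 | pre-contrast signal, constant across the image |
| `lesion_radius_range` | 12–20 px | circular lesion, central slice |
| `habitat_fractions` | 0.5/0.3/0.2 | rapid rim, medium ring, slow core (ring-enhancement pattern); count-true concentric assignment |
| amplitude range | 80–120% | peak relative enhancement of malignant lesions |
| `washout_slope` | 8–16 %/phase | type-III washout losing roughly one to two thirds of peak over the remaining phases |
| `amplitude_cv` | 0.10 | intralesional amplitude dispersion, negative class |
| `noise_sd` | 2 | additive Gaussian noise, intensity units |

Per-pixel curves are piecewise linear: wash-in from zero to the pixel
amplitude at its true TTP, then linear wash-out, floored at zero. Only the
argmax of the curve matters downstream, so curve shape beyond peak placement
is irrelevant; a pharmacokinetic model (Tofts etc.) would add parameters the
pipeline never reads. The washout default of 8–16 %/phase was fixed by the
stated calibration requirement that habitat recovery stay ≥ 95% when
noise-SD is 5% of amplitude: a flatter washout makes adjacent-phase
enhancement differences smaller than the phase-to-phase noise and recovery
sits near 93%; 8–16 is equally realistic and satisfies the requirement. It
was chosen once and is not revisited.

Two class-effect channels are separately switchable, so selectors can be
probed per channel: `texture_effect` widens the positive class's amplitude
dispersion (`cv × (1 + texture_effect)`), and `kinetic_effect` shifts the
positive habitat mix toward rapid. With both at zero the classes are
exchangeable — the null world used for permutation calibration. Defaults are
zero; the acceptance cohort uses `texture_effect = 2`, `kinetic_effect =
0.3` as its "strong effect".

The phantom does **not** emulate: Rician noise statistics (additive Gaussian
is a good approximation for subtraction images at moderate SNR, and no noise
model was published), coil sensitivity or B1 inhomogeneity, motion,
irregular lesion shapes, partial-volume boundaries, multi-slice anatomy, or
contrast-agent pharmacokinetics. A green phantom test therefore establishes
that the *computations* are correct and leakage-free and that the pipeline
recovers known structure under realistic noise — it does not establish
clinical performance, and published patient-data AUCs are deliberately not
reproduction targets (the underlying dataset is not publicly available).

## 6. Numerical and interface choices

* Pixel coordinates are 0-based, row-major, half-open in ROI boxes;
  post-contrast phases are 1-based. The analysis phases P-1/P-2/P-3 map
  fixedly to post-contrast phases 2/4/6.
* Each case's masks and phase images are plain CSV matrices with a cohort
  manifest CSV — deliberately text-only; no medical-image container
  (NIfTI/TIFF/PNG) reader is a hard dependency of this package.
* Per-phase segmentation can disagree across P-1/P-2/P-3; each phase's
  features use that phase's mask and subtraction image (the subregion
  features at P-k use the P-k image).
* Morphological opening can split a mask; the largest piece is kept so a
  lesion mask is always one connected component.
* Yates continuity correction is applied to all 2×2 chi-square tests — the
  only reading that reproduces the published cohort-table p-values (0.846,
  0.594) from the printed counts. Fisher's exact test enumerates the full
  (multivariate) hypergeometric support, with a 1e-7 relative tie tolerance.
* The DeLong paired test is used for correlated AUCs (the published z-test
  names no variant); confidence intervals use the DeLong variance with a
  normal approximation truncated to [0, 1]; the ROC operating point
  maximizes Youden's J with ties resolved toward higher specificity.
* ICC(2,1): two-way random effects, absolute agreement, single measure, with
  the conventional poor/moderate/good/excellent bands.

## 7. Known limitations

Single-slice 2-D analysis only; no 3-D segmentation or texture. No DICOM
ingestion. The stepwise selector refits a logistic model per candidate and
is the slow path at full feature width (use LASSO or PCA for large tables).
GLCM/GRLM level count, SVM kernel and cost, and the interval method of the
published univariate tables are all undocumented upstream; our choices are
stated above and exposed in configuration rather than hidden.
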