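---
title: "Methods: multi-site ultrasound texture and elastography classification of non-specific low back pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-site ultrasound texture and elastography classification of non-specific low back pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonolbp)
```

## The problem

Non-specific low back pain (NSLBP) is low back pain without an identified
physiological or pathological cause. Its severity is usually graded with the
Visual Analogue Scale (VAS, 0–10); a common clinical split is *mild*
(VAS ≤ 3) versus *moderate-severe* (VAS > 3). NSLBP involves several
paraspinal structures — the multifidus (MF), erector spinae (ES),
thoracolumbar fascia (TLF) and transversus abdominis (TrA) — so a single
ultrasound view is unlikely to carry all the discriminative information.

`sonolbp` implements a multi-site classification pipeline: B-mode ultrasound
texture features and shear-wave-elastography (SWE) summaries are extracted
from 14 regions of interest (ROIs) per subject, fused into one
800-dimensional feature vector, reduced by ANOVA-percentile selection, and
classified with a cross-validated linear support vector machine (SVM), with
moderate-severe pain as the positive class. The package also quantifies
which features, muscles, spine levels, sides and acquisition positions the
selected features come from, and compares multi-site fusion (MIFS) against
each single site (SIFS).

## Acquisition protocol

Each subject contributes 14 ROIs: MF imaged at the L2-L3 and L4-L5 levels on
both sides in both the prone and tabletop positions (8 images), and ES, TLF
and TrA imaged at L2-L3 on both sides in the prone position only (6 images).
Every ROI carries the B-mode image plus an SWE elasticity mean/std pair
(kPa) measured by the scanner; TLF and TrA additionally contribute one
side-averaged thickness each.

```{r}
roi_protocol()
```

## The feature bank

Each ROI yields 57 features; with 14 ROIs and the 2 thickness features a
protocol-complete subject has exactly 800:

| family | features | count |
|---|---|---|
| MFAF | spectral mean frequency (maximum-entropy and multi-window estimators) | 2 |
| First-order (FOS) | IOD, mean, std, variance, skewness, kurtosis, histogram energy | 7 |
| Haralick (GLCM) | contrast, correlation, energy, entropy, homogeneity, symmetry × 4 directions | 24 |
| Galloway (GLRLM) | SRE, LRE, GLNU, RLNU, RP × 4 directions | 20 |
| LBP | code-histogram energy and entropy | 2 |
| SWE | elasticity mean, std (pass-through scanner values) | 2 |

Thickness features are tallied under L2-L3/prone and are side-global, which
reproduces the attribution denominators of the full universe: MF 456 / ES
114 / TLF 115 / TrA 115; L2-L3 572 / L4-L5 228; prone 572 / tabletop 228;
L 399 / R 399 (+2 side-global).

Numerical conventions, chosen where the method leaves them open and recorded
in `extraction_params.json` by every pipeline run:

* **Quantization**: GLCM/GLRLM use `Q = 32` equal-width bins over
  `[0, 255]` (`floor(v * Q / 256)`, clipped). `Q` is a configuration knob.
* **GLCM**: distance 1, single-direction (non-symmetrized) accumulation at
  0°, 45°, 90°, 135°; normalization to sum 1. Non-symmetrized accumulation
  keeps the *symmetry* feature `1 − ½ Σ|P − Pᵀ|` informative — a symmetrized
  matrix would make it identically 1.
* **Haralick**: homogeneity uses the inverse-difference kernel
  `1 / (1 + |i − j|)`; entropies use natural logarithms; correlation is 0 by
  convention when a marginal is degenerate.
* **FOS**: population moments; skewness/kurtosis are 0 for a constant image;
  kurtosis is non-excess (a normal sample gives ≈ 3); IOD is the raw pixel
  sum; histogram energy uses the 256-bin normalized histogram.
* **Galloway**: raw run counts with `SRE = (1/N_r) Σ p/j²`,
  `LRE = (1/N_r) Σ p·j²`, `GLNU`, `RLNU`, `RP = N_r / n_pixels`. Runs are
  maximal constant-gray segments along each line of a direction; every pixel
  lies on exactly one line, so `Σ count × length = n_pixels` in all four
  directions.
* **LBP**: classic radius-1, 8-neighbour codes (bit set when neighbour ≥
  centre, starting east, counter-clockwise), raw 256-bin histogram (not
  uniform-pattern), interior pixels only.
* **MFAF**: columns are the axial direction (ultrasound texture periodicity
  is axial). The maximum-entropy estimator fits a Burg AR(8) model per
  mean-removed column and evaluates its spectral density on 256 points over
  `[0, 0.5]` cycles/pixel; the multi-window estimator averages 4
  sine-tapered periodograms. The per-column mean frequency is
  `Σ f·S(f) / Σ S(f)`; a column that is zero after mean removal gets the
  flat-spectrum value 0.25. The AR innovation variance cancels in the ratio,
  so only Burg coefficients are computed (in compiled code, verified against
  `stats::ar.burg` in the test suite). Burg order and taper count are
  configuration knobs.

## Standardization and feature selection

Features are z-scored, `y = (x − μ)/σ`, with population moments;
zero-variance columns map to 0. Each feature is then scored by the two-group
one-way ANOVA F-statistic (equal to the squared pooled-variance t-statistic)
and the top `percentile` % are retained, `k = floor(n × percentile / 100)`.
At the default `percentile = 6` on 800 features this retains exactly 48.
Ties are broken by canonical feature order; infinite F (zero within-group
variance with separation) ranks above all finite scores.

**Leakage control.** By default standardization parameters and F-scores are
fit on the training folds only and applied to held-out folds
(`selection_config(fit_on_all = FALSE)`). A single-pass mode that fits both
once on the whole dataset before cross-validation is provided
(`fit_on_all = TRUE`) because small-sample studies often standardize the
complete feature table up front; reports are labelled with the mode used.
Fold-wise fitting is the default because whole-data selection lets held-out
information influence the retained set, which biases cross-validated metrics
upward — the package's null-calibration tests (chance-level AUC on
effect-free cohorts) are run in the default mode.

## Classification and evaluation

A linear-kernel, L2-regularized soft-margin SVM (via `e1071`, i.e. libsvm
C-classification) is evaluated with stratified outer 5-fold
cross-validation. Within each outer training fold, the regularization
constant is chosen from `C ∈ {0.01, 0.1, 1, 10, 100}` by an inner stratified
5-fold grid search on accuracy (ties to the smallest C, favouring the wider
margin). Confusion counts use the decision threshold 0 on `w·x + b` and are
pooled over the outer folds; the AUC is computed from the pooled decision
scores by the rank (Mann-Whitney) statistic, because per-fold AUCs on ~10
held-out subjects are too unstable to average. The metric panel reports
accuracy, sensitivity, specificity, AUC, precision and NPV with
moderate-severe as positive.

Feature importance is the mean absolute SVM weight across outer folds (a
feature not selected in a fold contributes 0 there). Attribution tables
tally the whole-data optimal feature set by family, muscle, level, side and
position against the 800-name denominators. `sifs_table()` repeats the whole
protocol restricted to each single site's 57 features and appends the
all-site (MIFS) row.

`group_difference_tests()` reports per-feature two-sided p-values with a
Shapiro-Wilk normality gate (α = 0.05 per group) choosing between Student's
t-test and the Mann-Whitney test; the gate can be overridden with
`method = "t"` or `"wilcox"` when a specific branch is wanted.

## The synthetic cohort generator

No patient data ship with the package; the generator emulates the *data
structure* of the study so the whole pipeline is testable:

* **Cohort**: 24 mild + 28 moderate-severe subjects by default, with
  demographics sampled near the study's per-class moments (truncated at
  physiologic bounds) and VAS uniform on `[1, 3]` (mild) or `(3, 8]`
  (moderate-severe). Demographics are carried in the manifest but are not
  features.
* **B-mode ROIs** (64×64 px by default): a smooth anisotropic background
  (Gaussian-smoothed white noise, axial/lateral correlation lengths 2/4 px)
  multiplied by unit-mean gamma speckle (shape 4), log-compressed and
  affinely quantized to 0–255 — standard B-mode speckle phenomenology. The
  moderate-severe class scales correlation lengths by `1 + texture_effect`
  and the gamma shape by its inverse; `texture_effect = 0.15` by default, a
  subtle coarsening not readily visible by eye.
* **SWE**: log-normal elasticity with mild median 20 kPa, log-sd 0.2, and
  the moderate-severe median shifted up by `swe_effect` (default 6 kPa,
  reflecting the stiffer paraspinal tissue reported in LBP patients).
* **Thickness**: TLF 2.2 mm, TrA 4.0 mm baselines, moderate-severe reduced
  by `thickness_effect` (default 0.3 mm).

With all three effect knobs at 0 the classes are exchangeable in
distribution by construction (the class label only enters through
effect-scaled parameters), which is what the null-calibration tests exploit.
Effect sizes are free parameters: the source study reports no elasticity
magnitudes or texture effect sizes, so the defaults are plausible values
chosen once, not calibrated to its classification results. Under the default
effects the synthetic cohort is strongly separable — more separable than
real patients, where reported accuracy is far from perfect — so passing
tests demonstrate that the machinery recovers planted structure and is
calibrated under the null, not that real NSLBP data would reach any
particular accuracy.

The generator also does **not** emulate: acoustic wave propagation or RF
signals, operator-dependent ROI placement, inter-muscle differences in
baseline elasticity, within-subject correlation beyond the shared class
effect, or measurement repeatability error in SWE.

## Problem sizes and runtime choices

Simulation-based tests run the full pipeline on cohorts at the study size
(52 subjects, 14 ROIs of 64×64 px each) across 20 seeds per condition; the
null-calibration, effect-monotonicity, importance-dominance, family-fusion
and site-fusion checks share those runs. Unit tests use 10-subject,
32×32-px cohorts where only the plumbing is under test. Exhaustive oracle
checks enumerate all 512 binary 3×3 images for GLCM/GLRLM/FOS equivalence.

## Known limitations

* The decision threshold is fixed at 0; no probability calibration or
  threshold tuning is provided.
* Grid search optimizes accuracy only, and only over C — the kernel is
  deliberately fixed to linear.
* `percentile_sweep()` with the default nested evaluator needs each class to
  have at least `outer_folds` subjects per training fold; very small cohorts
  should pass a custom evaluator or a single-value `C_grid`.
* Feature names are parsed with a fixed grammar; user-supplied matrices with
  other column names work everywhere except the attribution tables.
* The synthetic generator is a stand-in: conclusions about real NSLBP
  classification performance cannot be drawn from synthetic panels.
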