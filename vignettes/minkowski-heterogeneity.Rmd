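---
title: "Minkowski-functional heterogeneity analysis of tumour MR images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minkowski-functional heterogeneity analysis of tumour MR images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfrad)
```

## The problem

After chemoradiotherapy for glioblastoma, an enlarging hyperintense lesion
on a T2-weighted MR image can mean either true tumour progression or
*pseudoprogression* — a transient, treatment-related change that later
stabilizes. The two demand opposite clinical responses, yet they are often
indistinguishable by eye. `mfrad` quantifies what the eye misses: the
*texture heterogeneity*, size and intensity statistics of the segmented
lesion, summarized through two-dimensional Minkowski functionals (MFs),
and feeds those descriptors to small-cohort classifiers with honest
leave-one-out evaluation.

## The model

### Threshold spectrum of Minkowski functionals

All ROI intensities of a tumour (over all slices) are mapped linearly onto
$[0,1]$ using a single tumour-wide minimum and maximum, so the same
thresholds are comparable across slices. The ladder of thresholds is
$t_i = (i-1)/11$, $i = 1..11$: ten equal steps starting from $t_1 = 0$, at
which every ROI pixel is white. A ROI pixel is white at threshold $t$ iff
its normalized value is $\ge t$ (ties go white, which is what makes the
first image all-white); pixels outside the ROI are excluded entirely
rather than treated as black, so every functional describes the segmented
region only.

Each binary image is viewed as a union of closed unit squares. With $p$,
$e$, $v$ the numbers of *distinct* faces, edges and vertices of that
union, the three 2D Minkowski functionals are

$$A = p, \qquad U = -4p + 2e, \qquad \chi = p - e + v,$$

area, boundary length (in pixel-edge units) and Euler characteristic
("genus": connected white regions, with diagonal neighbours counted as
connected, minus completely enclosed black regions). The identity
$\chi = p - e + v$ holds under exactly this dual convention —
8-connectivity for white, 4-connectivity for enclosed black — and the test
suite verifies it against an independent component-labelling oracle on
1000 random images, alongside a brute-force boundary-edge count for $U$.

Counts are summed over slices per threshold before applying the formulas,
and every functional is divided by the total ROI pixel count. Normalized
area at threshold 1 is then identically 1 and is dropped, leaving 10 area,
11 perimeter and 11 genus values: 32 MF features. Two size features
(`TotalArea`, the ROI pixel count; `TotalPerimeter`, the summed ROI
contour in pixel-edge units) and four signal-intensity features (mean, SD,
maximum, minimum of the *raw* intensities, each divided by the mean
intensity of a contralateral white-matter reference region) complete the
38-feature vector.

Two numerical conventions worth stating: a constant-intensity ROI
normalizes to all ones (every pixel white at every threshold — degenerate
but well defined), and the signal-intensity SD uses the population form
(divisor $N$), which keeps a single-pixel ROI well defined and a constant
ROI at exactly zero.

### Interpretation

`nPeri_1` is the ROI contour length per unit area — high values mean
irregular, frond-like margins. Mid-threshold `nPeri` values grow with
fine-grained intra-lesion texture: the more heterogeneous the region, the
more black/white boundary each threshold exposes. `nGenus` tracks the
fragmentation of the white phase into islands (positive) or the
appearance of enclosed dark holes (negative). Note that under pixel-count
normalization the genus values are typically far below 1; descriptions of
genus diverging "from unity" apply to the unnormalized count, not the
normalized feature reported here.

## Classification pipelines

Two parallel routes operate on a labelled cohort table
(progression = positive class throughout):

* **t-test → RBF-SVM.** Each feature is screened by a two-tailed,
  pooled-variance Student t-test at $P < 0.05$ (deliberately liberal, no
  multiple-testing correction by default; a Holm flag is available).
  Selected features are univariately z-scaled — test data are always
  scaled with the *training* statistics — and a radial-basis SVM is tuned
  over the LIBSVM-style grid $C = 2^{-5..15}$, $\gamma = 2^{-15..3}$
  (powers of two, step 2) by leave-one-out accuracy, ties broken towards
  the smallest $C$ then $\gamma$. The tuned parameters are then evaluated
  by the same leave-one-out loop, and held-out decision values feed the
  ROC analysis. Tuning and reporting on the same loop is the classical
  small-cohort protocol and is optimistically biased; under a label-null
  this bias is visible (see below), and `nested_loocv_accuracy()`
  implements the unbiased nested variant for readers who want it.

* **Random Forest → Lasso.** Features with raw permutation importance
  above the mean importance (a parameter-free threshold) are passed to an
  L1-penalized logistic regression, solved by an iteratively reweighted
  quadratic approximation with coordinate-wise soft-thresholding
  (convergence when the largest coefficient change falls below $10^{-6}$,
  capped at $10^4$ sweeps; a stalled, oscillating path or a coefficient
  hitting the divergence cap of 50 is flagged non-convergent). The
  penalty $\lambda$ is chosen by leave-one-out accuracy over
  $10^{0..-3}$ (16 log-spaced values), ties resolved towards the larger,
  sparser $\lambda$; held-out fits walk the path warm-started as
  coordinate-descent path algorithms conventionally do.

Accuracy is defined as $(TP+TN)/(TP+FP+TN+FN)$; accuracy, sensitivity and
specificity carry Wilson score intervals (exact 0/1 behaviour at the
boundaries), and AUC is the tie-aware Mann–Whitney statistic. All
stochastic fits require an explicit seed, which is recorded in the result.

## The phantom generator

No patient images ship with the package; every end-to-end claim is
exercised on synthetic multi-slice phantoms. Per slice, the ROI boundary
is $r(\theta) = R_j\,(1 + a\sum_m a_m \cos(m\theta + \varphi_m))$ with
random mode weights normalized by their maximum so the modulation attains
$\pm a$ exactly (without that normalization the $1/R$ size effect
dominates and the larger class cannot have the longer
contour-per-unit-area); slice radii follow a spherical-cap profile. The
interior is a hyperintense base level (1.6× the white-matter mean)
modulated by a Gaussian random field — white noise smoothed with an
isotropic Gaussian kernel of width `texture_corr_len`, rescaled to
`texture_sigma` — with circular dark foci (the imaging correlate of
microhaemorrhage/necrosis) punched in at a Poisson rate per 100 ROI
pixels. A square reference region of white-matter intensity sits in the
image corner. Everything derives from a single integer seed;
phantoms are bit-reproducible.

The default class contrast encodes the reported phenotype axes:
progression phantoms are larger (radius 16 vs 11 px), more frond-like
(amplitude 0.55, 12 modes vs 0.10, 4), more finely textured (σ 0.25,
correlation 1.5 px vs 0.12, 3 px), with more and deeper dark foci (rate
1.2/100 px at depth 0.7 vs 0.3 at 0.4) and hence a lower minimum signal
intensity. These magnitudes were fixed once, at design time, so that each
class-mean contrast points the way the phenotype description demands.

What the phantoms do *not* emulate: MR acquisition physics (no k-space,
coil or relaxation modelling), field-strength effects, partial-volume or
zero-filling interpolation, registration error, or anatomically realistic
lesion shapes. Passing end-to-end tests therefore demonstrates that the
pipeline recovers a *planted* morphological contrast through the full
feature–selection–classification chain — not that any particular clinical
accuracy would be attained on patient data.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use cohorts of 10 phantoms
per class with 4 slices each (unit tests use smaller 2-slice phantoms),
1000 random binary images up to 12×12 for the oracle suites, and the full
SVM grid (110 parameter pairs × leave-one-out). These sizes keep a
complete run in the low minutes on a single CPU while leaving every
statistical check well powered; they are stated here as the package's
reference configuration.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
cohort <- make_cohort(10, seed = 1)
features <- extract_cohort_features(cohort)
fit <- train_ttest_svm(features, seed = 1)
print(fit)

test_cohort <- make_cohort(10, seed = 2)
ev <- evaluate(fit, extract_cohort_features(test_cohort))
ev$metrics$accuracy
```

## Known limitations

* The genus convention requires the enclosed-black-region rule stated
  above; other connectivity pairings break $\chi = p - e + v$.
* Grey-scale normalization is per tumour. A per-slice variant can be
  obtained by processing slices as separate single-slice images, but
  cross-slice threshold comparability is then lost, and the package does
  not encourage it.
* The same-loop LOOCV protocol overstates accuracy when spurious features
  survive the screen; the null-cohort check in the acceptance suite
  therefore runs the classifier without the screen, and the nested
  variant is provided for unbiased reporting.
* Lesion masks are taken as authoritative; segmentation conventions
  (e.g. excluding cyst-like structures over 1 cm so cavities are not
  analysed as tissue) are the segmenter's responsibility.
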