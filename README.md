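# mfrad — Minkowski-functional heterogeneity analysis of tumour MR images

`mfrad` is an R toolkit for radiologists and imaging scientists who need
to quantify lesion heterogeneity in grey-scale MR images — the motivating
case being the separation of true glioblastoma progression from
pseudoprogression on routine T2-weighted follow-up scans, where the two
outcomes look alike to the eye but differ in texture, size and shape.

## What it computes

For each tumour (a multi-slice image plus a segmented ROI mask), the ROI
intensities are normalized onto [0, 1] tumour-wide and binarized at the
11 thresholds `t_i = (i − 1)/11`. Each black/white image is a union of
closed unit pixel squares with `p` faces, `e` distinct edges and `v`
distinct vertices, giving the three 2D Minkowski functionals

    A = p          (area)
    U = −4p + 2e   (black/white boundary length, pixel-edge units)
    χ = p − e + v  (genus: white components − enclosed black holes)

Counts are summed over slices and normalized by the ROI pixel count,
yielding 32 MF features (10 normalized areas, 11 perimeters, 11 genus
values), plus 2 size features (`TotalArea`, `TotalPerimeter`) and 4
signal-intensity features (mean/SD/max/min relative to a contralateral
white-matter reference): 38 features per tumour. Downstream, a t-test
screen feeds a radial-basis SVM tuned and evaluated by leave-one-out
cross-validation (Wilson score intervals, ROC AUC), with a parallel
Random-Forest → Lasso route; a synthetic phantom generator provides
fully labelled test cohorts. The methods vignette
(`vignettes/minkowski-heterogeneity.Rmd`) covers the model, conventions
and limitations in detail.

## Worked example

```r
library(mfrad)
cohort   <- make_cohort(10, seed = 1)          # 10 + 10 synthetic tumours
features <- extract_cohort_features(cohort)    # 20 x 38 feature table
fit      <- train_ttest_svm(features, seed = 1)
print(fit)
```

```
<mf_fit> ttest-svm | seed 1
  selected features (33): nArea_2, ..., nPeri_1, ..., TotalArea,
  TotalPerimeter, SImean, SIsd, SImax, SImin
  LOOCV accuracy: 20/20 = 100.0% (95% CI 83.9-100.0%)
  LOOCV ROC AUC: 1.000
```

The screen keeps 33 of 38 features — including the contour-per-unit-area
feature `nPeri_1`, the mid-threshold perimeters that track fine texture,
and both size features — and the cross-validated SVM separates the two
phantom classes perfectly (the planted contrast is deliberately strong).
The Wilson interval says that 20/20 held-out successes are still only
compatible with a true accuracy above ~84%. Held-out evaluation on a
fresh cohort uses the training-set scaling throughout:

```r
ev <- evaluate(fit, extract_cohort_features(make_cohort(10, seed = 2)))
ev$metrics$accuracy
#> $estimate [1] 1      $lower [1] 0.839    $upper [1] 1
#> $successes [1] 20    $n [1] 20
```

## Command line

A thin Rscript wrapper (`inst/cli/mfrad`, installed under
`system.file("cli", "mfrad", package = "mfrad")`) exposes the workflow:

```sh
mfrad simulate --out-dir phantoms --n-per-class 10 --seed 1
mfrad extract  --manifest phantoms/manifest.csv --out features.csv
mfrad train    --features features.csv --method ttest-svm --seed 1 \
               --out model.json --report report.txt
mfrad predict  --model model.json --features features.csv --out pred.csv
mfrad evaluate --model model.json --features features.csv
```

Every command accepts `--config FILE` (JSON defaults, overridden by
flags), writes its fully resolved configuration next to its outputs, and
demands an explicit `--seed` wherever randomness is involved.

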