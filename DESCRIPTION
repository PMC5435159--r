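Package: mfrad
Title: Minkowski-Functional Heterogeneity Analysis of Tumour MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies texture heterogeneity of segmented tumour regions in
    grey-scale MR images using two-dimensional Minkowski functionals (area,
    perimeter and genus) computed over a ladder of grey-scale thresholds,
    together with lesion size and signal-intensity descriptors. Includes
    t-test or Random-Forest feature selection, radial-basis support vector
    machine and L1-penalized logistic-regression classifiers evaluated by
    leave-one-out cross-validation with Wilson score intervals and ROC
    analysis, a synthetic multi-slice tumour phantom generator for end-to-end
    validation, and a command-line interface over the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    optparse,
    randomForest,
    RNifti,
    stats,
    utils
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
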