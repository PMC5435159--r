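#' Train the t-test + RBF-SVM classification pipeline
#'
#' The canonical analysis route: features are screened by two-tailed
#' unpaired Student t-tests at `P < alpha`, the selected features are
#' univariately z-scaled, and a radial-basis SVM is tuned and evaluated by
#' leave-one-out cross-validation ([svm_fit_loocv()]). The positive class
#' is progression throughout; sensitivity refers to detecting progression.
#'
#' @param features labelled feature `data.frame` (columns `tumour_id`,
#'   `label`, features), e.g. from [extract_cohort_features()] or
#'   [read_features_csv()].
#' @param alpha t-test selection threshold (default 0.05).
#' @param grid SVM parameter grid ([svm_grid()]).
#' @param seed mandatory integer seed, recorded in the result.
#' @param positive positive-class label.
#' @param correct multiple-testing correction for the screen
#'   (`"none"`, the default, or `"holm"`).
#' @return an object of class `"mf_fit"`.
#' @export
train_ttest_svm <- function(features, alpha = 0.05, grid = svm_grid(),
                            seed, positive = "progression",
                            correct = "none") {
  if (missing(seed)) {
    stop("parameter error: an explicit integer seed is required",
         call. = FALSE)
  }
  check_labels(features, positive)
  sel_tab <- ttest_select(features, alpha = alpha, positive = positive,
                          correct = correct)
  selected <- attr(sel_tab, "selected")
  if (length(selected) == 0) {
    stop("data error: no feature passed the t-test screen at alpha = ",
         alpha, call. = FALSE)
  }
  sc <- scale_features(features[c("tumour_id", "label", selected)])
  selected <- sc$stats$feature  # zero-variance features dropped
  fit <- svm_fit_loocv(as.matrix(sc$table[selected]), features$label,
                       grid = grid, seed = seed, positive = positive)
  fit$loocv <- cbind(tumour_id = features$tumour_id, fit$loocv)
  structure(
    c(list(method = "ttest-svm", positive = positive, selected = selected,
           scaling = sc$stats, selection = sel_tab, alpha = alpha), fit),
    class = "mf_fit"
  )
}

#' Train the Random-Forest + Lasso classification pipeline
#'
#' The alternate analysis route: features are selected by Random-Forest
#' permutation importance ([rf_select()]), z-scaled, and classified by
#' L1-penalized logistic regression with leave-one-out lambda selection
#' ([lasso_fit()]).
#'
#' @inheritParams train_ttest_svm
#' @param n_trees number of trees for the forest (default 1000).
#' @param lambda_grid lambda values for the Lasso search.
#' @return an object of class `"mf_fit"`.
#' @export
train_rf_lasso <- function(features, n_trees = 1000,
                           lambda_grid = default_lambda_grid(), seed,
                           positive = "progression") {
  if (missing(seed)) {
    stop("parameter error: an explicit integer seed is required",
         call. = FALSE)
  }
  check_labels(features, positive)
  sel_tab <- rf_select(features, n_trees = n_trees, seed = seed,
                       positive = positive)
  selected <- attr(sel_tab, "selected")
  if (length(selected) == 0) {
    stop("data error: Random-Forest selection returned no feature",
         call. = FALSE)
  }
  sc <- scale_features(features[c("tumour_id", "label", selected)])
  selected <- sc$stats$feature
  fit <- lasso_fit(as.matrix(sc$table[selected]), features$label,
                   lambda_grid = lambda_grid, seed = seed,
                   positive = positive)
  fit$loocv <- cbind(tumour_id = features$tumour_id, fit$loocv)
  structure(
    c(list(method = "rf-lasso", positive = positive, selected = selected,
           scaling = sc$stats, selection = sel_tab), fit),
    class = "mf_fit"
  )
}

#' @export
print.mf_fit <- function(x, ...) {
  cat("<mf_fit>", x$method, "| seed", x$seed, "\n")
  cat("  selected features (", length(x$selected), "): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  a <- x$metrics$accuracy
  cat(sprintf("  LOOCV accuracy: %d/%d = %.1f%% (95%% CI %.1f-%.1f%%)\n",
              a$successes, a$n, 100 * a$estimate, 100 * a$lower,
              100 * a$upper))
  cat(sprintf("  LOOCV ROC AUC: %.3f\n", x$auc))
  invisible(x)
}

#' Predict outcomes for new tumours
#'
#' Applies the training-set scaling statistics (never the test set's own)
#' to the selected features of `newdata`, then the stored classifier.
#' Positive decision values indicate the positive (progression) class.
#'
#' @param object an `mf_fit`.
#' @param newdata feature `data.frame` containing at least the selected
#'   feature columns.
#' @param ... unused.
#' @return `data.frame` with `tumour_id`, `decision`, `pred` (and `label`
#'   when present in `newdata`).
#' @export
predict.mf_fit <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) {
    stop("data error: empty test set", call. = FALSE)
  }
  missing_f <- setdiff(object$selected, names(newdata))
  if (length(missing_f) > 0) {
    stop("configuration error: feature(s) missing from test table: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(names(newdata),
                    c("tumour_id", "label", object$selected))
  sc <- scale_features(newdata[keep], stats = object$scaling)
  X <- as.matrix(sc$table[object$selected])
  dec <- model_decision(object$model, X)
  out <- data.frame(
    tumour_id = if ("tumour_id" %in% names(newdata)) newdata$tumour_id
                else seq_len(nrow(newdata)),
    decision = dec,
    pred = ifelse(dec > 0, object$positive, object$model$negative),
    stringsAsFactors = FALSE
  )
  if ("label" %in% names(newdata) && !anyNA(newdata$label)) {
    out$label <- newdata$label
  }
  out
}

#' Evaluate a trained model on a labelled test table
#'
#' Scales the test features with the training statistics, predicts, and
#' reports accuracy = (TP + TN) / (TP + FP + TN + FN), sensitivity and
#' specificity with Wilson score intervals, plus ROC AUC from the test
#' decision values.
#'
#' @param fit an `mf_fit`.
#' @param test labelled feature `data.frame`.
#' @param conf confidence level for the Wilson intervals.
#' @return list with `predictions`, `metrics` and `auc` (the AUC is `NA`
#'   when only one class is present in the test labels).
#' @export
evaluate <- function(fit, test, conf = 0.95) {
  stopifnot(inherits(fit, "mf_fit"))
  if (nrow(test) == 0) {
    stop("data error: empty test set", call. = FALSE)
  }
  if (!"label" %in% names(test) || anyNA(test$label)) {
    stop("data error: evaluation requires a labelled test table",
         call. = FALSE)
  }
  preds <- predict(fit, test)
  metrics <- classification_metrics(preds$label, preds$pred, fit$positive,
                                    conf)
  auc <- if (length(unique(preds$label)) == 2) {
    roc_auc(preds$decision, preds$label, fit$positive)
  } else NA_real_
  list(predictions = preds, metrics = metrics, auc = auc)
}

#' Serialize / restore a trained model as JSON
#'
#' The JSON file carries everything needed to reproduce predictions in a
#' fresh session: method, selected features, training scaling statistics,
#' classifier parameters (support vectors / coefficients / rho for the
#' SVM; weights and intercept for the Lasso), leave-one-out predictions,
#' metrics and the seed. A model restored with `read_model_json()`
#' predicts identically to the in-memory original.
#'
#' @param fit an `mf_fit`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); an `mf_fit` (reader).
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "mf_fit"))
  obj <- unclass(fit)
  obj$selection <- NULL  # full selection table kept out of the model file
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$scaling <- as.data.frame(obj$scaling, stringsAsFactors = FALSE)
  if (obj$model$type == "rbf-svm") {
    if (is.list(obj$model$SV)) {
      obj$model$SV <- do.call(rbind, lapply(obj$model$SV, unlist))
    }
    obj$model$SV <- matrix(as.numeric(obj$model$SV),
                           ncol = length(obj$selected))
    obj$model$coefs <- as.numeric(unlist(obj$model$coefs))
  }
  if (!is.null(obj$model$beta)) {
    obj$model$beta <- as.numeric(unlist(obj$model$beta))
    names(obj$model$beta) <- obj$selected
  }
  structure(obj, class = "mf_fit")
}
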