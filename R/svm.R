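#' Default RBF-SVM parameter grid
#'
#' Powers-of-two grid over cost and kernel width, the standard LIBSVM
#' search range: `C = 2^-5 .. 2^15`, `gamma = 2^-15 .. 2^3`, in steps of 2
#' in the exponent.
#'
#' @param cost_exp exponents for `C = 2^cost_exp`.
#' @param gamma_exp exponents for `gamma = 2^gamma_exp`.
#' @return `data.frame` with columns `cost` and `gamma`, ordered by
#'   increasing cost then gamma (the tie-break order of the search).
#' @export
svm_grid <- function(cost_exp = seq(-5, 15, by = 2),
                     gamma_exp = seq(-15, 3, by = 2)) {
  g <- expand.grid(gamma = 2^gamma_exp, cost = 2^cost_exp)
  g <- g[order(g$cost, g$gamma), c("cost", "gamma")]
  rownames(g) <- NULL
  g
}

svm_one <- function(x, y, cost, gamma) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# Raw RBF decision values from stored support-vector parameters; matches
# LIBSVM's reported decision values (sign handled by the caller via `flip`).
rbf_decision_raw <- function(X, SV, coefs, rho, gamma) {
  X <- as.matrix(X)
  SV <- as.matrix(SV)
  d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * X %*% t(SV)
  K <- exp(-gamma * pmax(d2, 0))
  drop(K %*% coefs) - rho
}

svm_params <- function(m, positive) {
  pred <- stats::predict(m, m$SV[1, , drop = FALSE], decision.values = TRUE)
  cn <- colnames(attr(pred, "decision.values"))
  flip <- !startsWith(cn, positive)
  list(type = "rbf-svm", cost = m$cost, gamma = m$gamma,
       SV = unname(as.matrix(m$SV)), coefs = drop(m$coefs), rho = m$rho,
       flip = flip)
}

model_decision <- function(model, X) {
  if (model$type == "rbf-svm") {
    d <- rbf_decision_raw(X, model$SV, model$coefs, model$rho, model$gamma)
    if (isTRUE(model$flip)) -d else d
  } else if (model$type == "lasso-logistic") {
    drop(model$beta0 + as.matrix(X) %*% model$beta)
  } else {
    stop("unknown model type: ", model$type, call. = FALSE)
  }
}

#' Radial-basis SVM with leave-one-out parameter optimization
#'
#' Grid-searches `(C, gamma)` by leave-one-out cross-validated accuracy,
#' breaking ties towards the smallest cost and then the smallest gamma;
#' refits the model on all rows at the chosen parameters; and retains the
#' held-out decision values at those parameters for ROC analysis and
#' downstream use. Note that parameters are tuned and reported on the same
#' leave-one-out loop (the classical protocol for small cohorts); see
#' [nested_loocv_accuracy()] for the unbiased variant.
#'
#' @param x scaled numeric feature matrix (rows = samples).
#' @param y two-class labels.
#' @param grid parameter grid from [svm_grid()].
#' @param seed integer seed recorded in the result.
#' @param positive positive-class label (default `"progression"`).
#' @return list with `model` (support vectors, coefficients, rho, cost,
#'   gamma), `loocv` data frame of held-out predictions and decision
#'   values, `metrics` (accuracy / sensitivity / specificity with Wilson
#'   intervals), `auc`, `grid_search` (per-combination accuracies), `seed`.
#' @export
svm_fit_loocv <- function(x, y, grid = svm_grid(), seed,
                          positive = "progression") {
  if (missing(seed)) {
    stop("parameter error: an explicit integer seed is required",
         call. = FALSE)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  classes <- unique(as.character(y))
  if (length(classes) != 2) {
    stop("data error: exactly two classes required for SVM fitting",
         call. = FALSE)
  }
  if (min(table(y)) < 2) {
    stop("data error: each class needs at least 2 samples for LOOCV",
         call. = FALSE)
  }
  yf <- factor(as.character(y), levels = c(positive,
                                           setdiff(classes, positive)))
  set.seed(seed)
  acc <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    correct <- 0
    for (i in seq_len(n)) {
      m <- svm_one(x[-i, , drop = FALSE], yf[-i], grid$cost[k],
                   grid$gamma[k])
      p <- stats::predict(m, x[i, , drop = FALSE])
      correct <- correct + (as.character(p) == as.character(yf[i]))
    }
    acc[k] <- correct / n
  }
  best <- which.max(acc)  # grid ordered by (cost, gamma): ties go smallest
  cost <- grid$cost[best]
  gamma <- grid$gamma[best]
  # held-out decision values at the chosen parameters
  dec <- numeric(n)
  pred <- character(n)
  for (i in seq_len(n)) {
    m <- svm_one(x[-i, , drop = FALSE], yf[-i], cost, gamma)
    par <- svm_params(m, positive)
    dec[i] <- model_decision(par, x[i, , drop = FALSE])
    pred[i] <- if (dec[i] > 0) positive else setdiff(classes, positive)
  }
  final <- svm_one(x, yf, cost, gamma)
  model <- svm_params(final, positive)
  metrics <- classification_metrics(as.character(yf), pred, positive)
  list(model = c(model, list(positive = positive,
                             negative = setdiff(classes, positive))),
       loocv = data.frame(label = as.character(yf), pred = pred,
                          decision = dec, stringsAsFactors = FALSE),
       metrics = metrics,
       auc = roc_auc(dec, as.character(yf), positive),
       grid_search = cbind(grid, loocv_accuracy = acc),
       seed = seed)
}

#' Nested leave-one-out accuracy
#'
#' For each held-out sample, the full `(C, gamma)` grid search (itself by
#' inner leave-one-out) is repeated on the remaining samples before
#' predicting the held-out one. This removes the optimistic bias of tuning
#' and reporting on the same loop, at quadratic cost in the sample count.
#'
#' @inheritParams svm_fit_loocv
#' @return list with `accuracy` ([wilson_interval()]) and the per-sample
#'   predictions.
#' @export
nested_loocv_accuracy <- function(x, y, grid = svm_grid(), seed,
                                  positive = "progression") {
  x <- as.matrix(x)
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    inner <- svm_fit_loocv(x[-i, , drop = FALSE], y[-i], grid, seed,
                           positive)
    dec <- model_decision(inner$model, x[i, , drop = FALSE])
    pred[i] <- if (dec > 0) positive else inner$model$negative
  }
  list(accuracy = wilson_interval(sum(pred == y), n),
       predictions = data.frame(label = y, pred = pred,
                                stringsAsFactors = FALSE))
}
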