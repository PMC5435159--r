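#' L1-penalized logistic regression (core solver)
#'
#' Minimizes `-(1/n) loglik(beta0, beta) + lambda * sum(|beta|)` by an
#' iteratively reweighted quadratic (Newton-type) approximation with
#' coordinate-wise soft-thresholding updates; the intercept is unpenalized.
#' Iteration stops when the largest coefficient change falls below `tol`
#' (default 1e-6) or after `max_iter` (default 1e4) sweeps. On separable
#' data at lambda near 0 the unpenalized optimum diverges; the solver then
#' caps coefficients at `cap` and returns `converged = FALSE` rather than
#' erroring, so a surrounding lambda search can continue.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y01 0/1 response (1 = positive class).
#' @param lambda non-negative penalty.
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_iter iteration cap.
#' @param cap absolute bound applied to coefficients (divergence guard).
#' @param init optional warm start: list with `beta0` and `beta` from a
#'   previous fit (e.g. at a neighbouring lambda).
#' @return list with `beta0`, `beta` (named), `converged`, `iterations`.
#' @export
lasso_logistic <- function(x, y01, lambda, tol = 1e-6, max_iter = 1e4,
                           cap = 50, init = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (length(y01) != n || !all(y01 %in% c(0, 1))) {
    stop("parameter error: y01 must be a 0/1 vector matching nrow(x)",
         call. = FALSE)
  }
  if (lambda < 0) {
    stop("parameter error: lambda must be non-negative", call. = FALSE)
  }
  if (is.null(init)) {
    beta0 <- stats::qlogis(max(min(mean(y01), 1 - 1e-6), 1e-6))
    beta <- rep(0, k)
  } else {
    beta0 <- init$beta0
    beta <- unname(init$beta)
  }
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  it <- 0
  converged <- FALSE
  capped <- FALSE
  min_delta <- Inf
  last_improve <- 0
  eta <- drop(beta0 + x %*% beta)
  repeat {
    it <- it + 1
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-5)
    z <- eta + (y01 - pr) / w
    r <- z - eta  # working residual, kept in sync incrementally
    max_delta <- 0
    # intercept (unpenalized weighted mean of the working residual)
    d0 <- sum(w * r) / sum(w)
    beta0 <- beta0 + d0
    eta <- eta + d0
    r <- r - d0
    max_delta <- max(max_delta, abs(d0))
    for (j in seq_len(k)) {
      num <- sum(w * x[, j] * (r + x[, j] * beta[j])) / n
      den <- sum(w * x[, j]^2) / n
      newb <- soft(num, lambda) / den
      if (abs(newb) > cap) capped <- TRUE
      newb <- max(min(newb, cap), -cap)
      d <- newb - beta[j]
      if (d != 0) {
        beta[j] <- newb
        eta <- eta + x[, j] * d
        r <- r - x[, j] * d
      }
      max_delta <- max(max_delta, abs(d))
    }
    if (max_delta < tol) {
      converged <- TRUE
      break
    }
    if (max_delta < min_delta * 0.999) {
      min_delta <- max_delta
      last_improve <- it
    }
    # oscillating (non-shrinking) updates: treat as non-convergent early
    if (it - last_improve >= 100) break
    if (it >= max_iter) break
  }
  names(beta) <- colnames(x)
  # a solution stuck at the cap is a divergence guard, not a stationary point
  list(beta0 = beta0, beta = beta, converged = converged && !capped,
       iterations = it)
}

default_lambda_grid <- function() 10^seq(0, -3, length.out = 16)

#' Lasso classifier with leave-one-out lambda selection
#'
#' Fits an L1-penalized logistic regression ([lasso_logistic()]) on scaled
#' features for each lambda of the grid, scores each lambda by
#' leave-one-out cross-validated accuracy (a held-out sample is predicted
#' positive when its linear predictor exceeds 0), and picks the accuracy
#' maximizer, breaking ties towards the larger (sparser) lambda. The final
#' model is refit on all rows at the chosen lambda; held-out decision
#' values at that lambda feed the ROC analysis.
#'
#' @param x scaled numeric feature matrix.
#' @param y labels; `positive` marks the positive class.
#' @param lambda_grid decreasing or arbitrary positive lambda values
#'   (default `10^seq(0, -4, length.out = 25)`).
#' @param seed integer seed recorded in the result (the solver itself is
#'   deterministic).
#' @param positive positive-class label.
#' @return an `mf_fit`-compatible list: `model` (type, lambda, beta0,
#'   beta), `loocv` data frame, `metrics`, `auc`, `lambda_path`.
#' @export
lasso_fit <- function(x, y, lambda_grid = default_lambda_grid(), seed,
                      positive = "progression") {
  if (missing(seed)) {
    stop("parameter error: an explicit integer seed is required",
         call. = FALSE)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(unique(y)) != 2) {
    stop("data error: exactly two classes required", call. = FALSE)
  }
  y01 <- as.integer(y == positive)
  grid <- sort(unique(lambda_grid), decreasing = TRUE)
  # held-out fits walk the lambda path warm-started from the previous
  # lambda, as coordinate-descent path algorithms conventionally do
  dec <- matrix(NA_real_, length(grid), n)
  conv <- matrix(NA, length(grid), n)
  for (i in seq_len(n)) {
    warm <- NULL
    for (g in seq_along(grid)) {
      fit <- lasso_logistic(x[-i, , drop = FALSE], y01[-i], grid[g],
                            init = warm)
      warm <- fit[c("beta0", "beta")]
      conv[g, i] <- fit$converged
      dec[g, i] <- fit$beta0 + sum(x[i, ] * fit$beta)
    }
  }
  path <- lapply(seq_along(grid), function(g) {
    list(acc = mean((dec[g, ] > 0) == (y01 == 1)), dec = dec[g, ],
         converged = all(conv[g, ]))
  })
  accs <- vapply(path, `[[`, numeric(1), "acc")
  best <- which.max(accs)  # grid is decreasing, so ties pick larger lambda
  lambda <- grid[best]
  final <- lasso_logistic(x, y01, lambda)
  if (!final$converged) {
    stop("non-convergence at selected lambda ", signif(lambda, 4),
         " after ", final$iterations, " iterations", call. = FALSE)
  }
  dec <- path[[best]]$dec
  pred <- ifelse(dec > 0, positive, setdiff(unique(y), positive))
  metrics <- classification_metrics(y, pred, positive)
  list(model = list(type = "lasso-logistic", lambda = lambda,
                    beta0 = final$beta0, beta = final$beta,
                    positive = positive,
                    negative = setdiff(unique(y), positive)),
       loocv = data.frame(label = y, pred = pred, decision = dec,
                          stringsAsFactors = FALSE),
       metrics = metrics,
       auc = roc_auc(dec, y, positive),
       lambda_path = data.frame(lambda = grid, loocv_accuracy = accs,
                                converged = vapply(path, `[[`, logical(1),
                                                   "converged")),
       seed = seed)
}
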