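#' Wilson score interval for a binomial proportion
#'
#' Closed-form Wilson interval. The bounds behave correctly at the
#' boundaries: 0 successes gives a lower bound of exactly 0 and n successes
#' an upper bound of exactly 1.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param conf confidence level, default 0.95.
#' @return named list with `estimate`, `lower`, `upper`, `successes`, `n`.
#' @export
#' @examples
#' wilson_interval(15, 17)
wilson_interval <- function(successes, n, conf = 0.95) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("parameter error: n must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(successes) || length(successes) != 1 ||
      successes < 0 || successes > n || successes != round(successes)) {
    stop("parameter error: successes must lie in 0..n", call. = FALSE)
  }
  if (conf <= 0 || conf >= 1) {
    stop("parameter error: conf must lie in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  list(estimate = phat,
       lower = max(0, centre - half),
       upper = min(1, centre + half),
       successes = successes, n = n)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of continuous decision values against
#' binary labels; tied decision values contribute 1/2 per tied pair.
#'
#' @param decision_values numeric scores, larger meaning more
#'   positive-class-like.
#' @param labels class labels; values equal to `positive` form the positive
#'   class.
#' @param positive the positive-class label (default `"progression"`).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(decision_values, labels, positive = "progression") {
  if (length(decision_values) != length(labels)) {
    stop("parameter error: decision values and labels differ in length",
         call. = FALSE)
  }
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("parameter error: both classes must be present for ROC analysis",
         call. = FALSE)
  }
  r <- rank(decision_values)  # average ranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics with Wilson intervals
#'
#' Accuracy is (TP + TN) / (TP + FP + TN + FN); sensitivity is the fraction
#' of true positive-class samples predicted positive, specificity the
#' fraction of true negative-class samples predicted negative. Each comes
#' with a Wilson score interval.
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param positive positive-class label.
#' @param conf confidence level for the Wilson intervals.
#' @return list with elements `accuracy`, `sensitivity`, `specificity`
#'   (each a [wilson_interval()] result) and the 2x2 `confusion` table.
#' @export
classification_metrics <- function(truth, predicted,
                                   positive = "progression", conf = 0.95) {
  if (length(truth) != length(predicted) || length(truth) == 0) {
    stop("parameter error: truth and predicted must be non-empty and of ",
         "equal length", call. = FALSE)
  }
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  n <- length(truth)
  out <- list(accuracy = wilson_interval(tp + tn, n, conf))
  out$sensitivity <- if (tp + fn > 0) wilson_interval(tp, tp + fn, conf)
  out$specificity <- if (tn + fp > 0) wilson_interval(tn, tn + fp, conf)
  out$confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(truth = c(positive, "other"),
                                          predicted = c(positive, "other")))
  out
}
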