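feature_columns <- function(table) {
  setdiff(names(table), c("tumour_id", "label"))
}

check_labels <- function(table, positive = "progression") {
  if (!"label" %in% names(table) || anyNA(table$label)) {
    stop("data error: cohort table must carry a label for every row",
         call. = FALSE)
  }
  labs <- unique(table$label)
  if (length(labs) != 2) {
    stop("data error: exactly two classes required, found ",
         length(labs), call. = FALSE)
  }
  if (!positive %in% labs) {
    stop("data error: positive class '", positive, "' absent from labels",
         call. = FALSE)
  }
  invisible(labs)
}

#' Univariate z-scaling of a feature table
#'
#' Centres and scales each feature column to zero mean and unit standard
#' deviation. When `stats` from a previous (training) call is supplied, its
#' means and standard deviations are applied unchanged, as required for test
#' data. Zero-variance features cannot be scaled and are dropped with a
#' warning when learning the statistics.
#'
#' @param table feature `data.frame` (with optional `tumour_id` / `label`
#'   columns, which are passed through untouched).
#' @param stats optional scaling statistics from a previous call.
#' @return list with `table` (scaled), `stats` (`data.frame` of feature,
#'   mean, sd) and `dropped` (names of zero-variance features removed).
#' @export
scale_features <- function(table, stats = NULL) {
  feats <- feature_columns(table)
  if (is.null(stats)) {
    mu <- vapply(table[feats], mean, numeric(1))
    sd_ <- vapply(table[feats], stats::sd, numeric(1))
    dropped <- feats[sd_ == 0 | !is.finite(sd_)]
    if (length(dropped) > 0) {
      warning("dropping zero-variance feature(s): ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    keep <- setdiff(feats, dropped)
    stats <- data.frame(feature = keep, mean = mu[keep], sd = sd_[keep],
                        stringsAsFactors = FALSE, row.names = NULL)
  } else {
    missing <- setdiff(stats$feature, feats)
    if (length(missing) > 0) {
      stop("configuration error: feature(s) absent from table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    dropped <- setdiff(feats, stats$feature)
  }
  out <- table[c(intersect(names(table), c("tumour_id", "label")))]
  for (i in seq_len(nrow(stats))) {
    f <- stats$feature[i]
    out[[f]] <- (table[[f]] - stats$mean[i]) / stats$sd[i]
  }
  list(table = out, stats = stats, dropped = dropped)
}

#' Feature selection by two-tailed unpaired Student t-tests
#'
#' Compares each feature between the two outcome classes with a pooled-
#' variance two-sample t-test and keeps features with `P < alpha`. No
#' multiple-testing correction is applied by default (the working threshold
#' is a deliberately liberal screen ahead of the classifier); `correct =
#' "holm"` switches on a Holm adjustment. A feature that is identical in
#' both classes is reported with t = 0, P = 1 and is never selected.
#'
#' @param table labelled feature `data.frame`; each class needs >= 2 rows.
#' @param alpha significance threshold (default 0.05).
#' @param positive positive-class label.
#' @param correct `"none"` (default) or `"holm"`.
#' @return `data.frame` with one row per feature: `feature`, `t`, `df`,
#'   `p`, `neg_log10_p`, `selected`. The selected names (in input order) are
#'   in attribute `"selected"`.
#' @export
ttest_select <- function(table, alpha = 0.05, positive = "progression",
                         correct = c("none", "holm")) {
  correct <- match.arg(correct)
  check_labels(table, positive)
  feats <- feature_columns(table)
  grp <- table$label == positive
  if (sum(grp) < 2 || sum(!grp) < 2) {
    stop("data error: each class needs at least 2 samples for t-tests",
         call. = FALSE)
  }
  res <- lapply(feats, function(f) {
    x <- table[[f]][grp]
    y <- table[[f]][!grp]
    tt <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # both groups essentially constant at the same value
      data.frame(feature = f, t = 0, df = length(x) + length(y) - 2, p = 1)
    } else {
      data.frame(feature = f, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  })
  res <- do.call(rbind, res)
  p_used <- if (correct == "holm") stats::p.adjust(res$p, "holm") else res$p
  res$neg_log10_p <- -log10(res$p)
  res$selected <- p_used < alpha
  attr(res, "selected") <- res$feature[res$selected]
  res
}

#' Feature selection by Random-Forest permutation importance
#'
#' Grows a random forest on the labelled table and ranks features by raw
#' (unscaled) permutation importance (mean decrease in out-of-bag
#' accuracy). Features with importance above the mean importance are
#' selected — a parameter-free threshold that is stable at this feature
#' count. With pure-noise features the selection is unstable by nature; the
#' recorded importances are always returned.
#'
#' @param table labelled feature `data.frame`.
#' @param n_trees number of trees (default 1000).
#' @param seed integer RNG seed (mandatory: forests are stochastic).
#' @param positive positive-class label.
#' @return `data.frame` with `feature`, `importance`, `selected`, ordered
#'   by decreasing importance; selected names in attribute `"selected"`,
#'   the threshold in attribute `"threshold"`.
#' @export
rf_select <- function(table, n_trees = 1000, seed, positive = "progression") {
  if (missing(seed)) {
    stop("parameter error: an explicit integer seed is required",
         call. = FALSE)
  }
  check_labels(table, positive)
  feats <- feature_columns(table)
  x <- as.matrix(table[feats])
  y <- factor(table$label == positive, levels = c(FALSE, TRUE),
              labels = c("other", positive))
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  thr <- mean(imp)
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    selected = unname(imp) > thr, stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "selected") <- out$feature[out$selected]
  attr(out, "threshold") <- thr
  out
}
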