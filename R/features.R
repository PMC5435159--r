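#' Names of the 38 tumour features
#'
#' Ten normalized areas (thresholds 2..11), eleven normalized perimeters and
#' eleven normalized genus values (thresholds 1..11), two size features and
#' four signal-intensity features.
#'
#' @param n_levels number of grey-scale thresholds (default 11).
#' @return character vector of feature names.
#' @export
mf_feature_names <- function(n_levels = 11) {
  c(paste0("nArea_", 2:n_levels),
    paste0("nPeri_", 1:n_levels),
    paste0("nGenus_", 1:n_levels),
    "TotalArea", "TotalPerimeter",
    "SImean", "SIsd", "SImax", "SImin")
}

#' Lesion size features
#'
#' `TotalArea` is the summed white-pixel area at grey-scale threshold 1
#' (i.e. the ROI pixel count over all slices) and `TotalPerimeter` the
#' summed perimeter at threshold 1 (the ROI contour length over all slices,
#' in pixel-edge units). With `units = "mm"` and spacing metadata present,
#' the counts are converted to mm^2 / mm; this conversion never enters the
#' normalized Minkowski functionals.
#'
#' @param img a [tumour_image()].
#' @param units `"pixel"` (default) or `"mm"`.
#' @return named numeric vector `c(TotalArea, TotalPerimeter)`.
#' @export
size_features <- function(img, units = c("pixel", "mm")) {
  stopifnot(inherits(img, "tumour_image"))
  units <- match.arg(units)
  TA <- 0
  TP <- 0
  for (m in img$roi) {
    cc <- count_cells(m == 1)
    mf <- minkowski_2d(cc["p"], cc["e"], cc["v"])
    TA <- TA + mf[["A"]]
    TP <- TP + mf[["U"]]
  }
  if (units == "mm") {
    if (is.null(img$spacing) || is.null(img$spacing$pixel)) {
      stop("configuration error: mm units requested but no pixel spacing ",
           "metadata present", call. = FALSE)
    }
    px <- img$spacing$pixel
    if (length(px) == 1) px <- c(px, px)
    TA <- TA * px[1] * px[2]
    TP <- TP * mean(px)
  }
  c(TotalArea = TA, TotalPerimeter = TP)
}

#' Signal-intensity features
#'
#' Mean, standard deviation, maximum and minimum of the raw ROI intensities
#' pooled over all slices, each expressed as a ratio to the reference
#' (contralateral white matter) mean. The standard deviation is the
#' population form (divisor N), consistent with the 1/TotalArea
#' normalization of the mean, so a constant ROI has SIsd = 0 and a
#' single-pixel ROI is well defined.
#'
#' @param img a [tumour_image()].
#' @param ref_mean positive scalar reference intensity (see
#'   [reference_mean()]).
#' @return named numeric vector `c(SImean, SIsd, SImax, SImin)`.
#' @export
si_features <- function(img, ref_mean) {
  stopifnot(inherits(img, "tumour_image"))
  if (!is.numeric(ref_mean) || length(ref_mean) != 1 ||
      !is.finite(ref_mean) || ref_mean <= 0) {
    stop("parameter error: ref_mean must be a positive finite scalar",
         call. = FALSE)
  }
  vals <- unlist(mapply(function(s, m) s[m == 1], img$slices, img$roi,
                        SIMPLIFY = FALSE))
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  c(SImean = mu, SIsd = sigma, SImax = max(vals), SImin = min(vals)) /
    ref_mean
}

#' Extract the full 38-feature vector of one tumour
#'
#' Composes grey-scale normalization, the threshold ladder, the
#' Minkowski-functional spectrum and the size and signal-intensity features
#' into one named row: 32 MF features, 2 size features and 4
#' signal-intensity features.
#'
#' @param img a [tumour_image()].
#' @param ref reference for the signal-intensity features: `NULL` to use the
#'   image's own reference mask, or an explicit positive scalar mean.
#' @param n_levels number of grey-scale thresholds (default 11).
#' @return a one-row `data.frame` with columns `tumour_id`, `label` and the
#'   38 features named as in [mf_feature_names()]. The threshold ladder and
#'   normalization bounds are attached as the `"provenance"` attribute.
#' @export
#' @examples
#' img <- tumour_image(matrix(runif(64, 50, 150), 8, 8), matrix(1, 8, 8),
#'                     tumour_id = "t1")
#' f <- extract_features(img, ref = 100)
#' ncol(f) - 2  # 38 features
extract_features <- function(img, ref = NULL, n_levels = 11) {
  stopifnot(inherits(img, "tumour_image"))
  rm_ <- if (is.null(ref)) reference_mean(img) else reference_mean(ref)
  norm <- normalize_roi(img)
  thresholds <- threshold_sequence(n_levels)
  spec <- mf_spectrum(norm, thresholds)
  feats <- c(spec$nArea, spec$nPeri, spec$nGenus, size_features(img),
             si_features(img, rm_))
  stopifnot(identical(names(feats), mf_feature_names(n_levels)))
  out <- data.frame(tumour_id = img$tumour_id, label = img$label,
                    as.list(feats), stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "provenance") <- list(
    thresholds = thresholds, lo = norm$lo, hi = norm$hi,
    n_pixels_total = norm$n_pixels_total, ref_mean = rm_
  )
  out
}

#' Extract features for every tumour of a cohort
#'
#' @param cohort a `labelled_cohort` from [make_cohort()], or a list of
#'   [tumour_image()] objects.
#' @param ref optional explicit scalar reference mean applied to all images
#'   (default: each image's own reference mask).
#' @param n_levels number of grey-scale thresholds.
#' @return a `data.frame` with one row per tumour.
#' @export
extract_cohort_features <- function(cohort, ref = NULL, n_levels = 11) {
  imgs <- if (inherits(cohort, "labelled_cohort")) cohort$images else cohort
  rows <- lapply(imgs, extract_features, ref = ref, n_levels = n_levels)
  do.call(rbind, rows)
}

#' Write / read a cohort feature table
#'
#' Plain CSV with one row per tumour (`tumour_id`, `label`, 38 feature
#' columns). `write_features_csv()` also writes a JSON provenance sidecar
#' (`<path>.json`) recording the threshold ladder and, per tumour, the
#' normalization bounds and reference mean when available.
#'
#' @param features feature `data.frame` as built by
#'   [extract_cohort_features()].
#' @param path CSV file path.
#' @param provenance optional list stored in the sidecar.
#' @return `path`, invisibly (writer); the feature `data.frame` (reader).
#' @export
write_features_csv <- function(features, path, provenance = NULL) {
  utils::write.csv(features, path, row.names = FALSE)
  side <- list(feature_names = setdiff(names(features),
                                       c("tumour_id", "label")),
               n_tumours = nrow(features))
  if (!is.null(provenance)) side$provenance <- provenance
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"tumour_id" %in% names(df)) {
    stop("data error: feature table lacks a tumour_id column", call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  feat_cols <- setdiff(names(df), c("tumour_id", "label"))
  if (anyNA(df[feat_cols])) {
    stop("data error: feature table contains missing values", call. = FALSE)
  }
  df
}
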