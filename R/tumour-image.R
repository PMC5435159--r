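#' Construct a multi-slice tumour image
#'
#' Bundles the grey-scale slices of one tumour with its region-of-interest
#' (ROI) mask and an optional reference mask over normal-appearing
#' contralateral white matter. The ROI is the manually segmented
#' T2-hyperintense pathological region; all downstream Minkowski-functional
#' and signal-intensity features are computed from the pixels under it.
#'
#' Cyst-like structures larger than 1 cm in diameter are conventionally
#' excluded at segmentation time so that tissue rather than resection or
#' necrotic cavities is analysed; the supplied mask is treated as
#' authoritative and this rule is not automated.
#'
#' @param slices a 2D numeric matrix or a list of 2D numeric matrices
#'   (one per slice, in acquisition order); intensities must be finite and
#'   non-negative (arbitrary units).
#' @param roi binary mask (values 0/1 or logical) matching `slices` in
#'   shape: a matrix or list of matrices. Must be non-empty on at least one
#'   slice.
#' @param reference optional binary mask of normal reference tissue; a single
#'   matrix (applied to the first slice) or a list matching `slices`.
#' @param spacing optional named list with elements `pixel` (in-plane pixel
#'   size, mm), `thickness` and `gap` (slice thickness and inter-slice gap,
#'   mm). Used only for optional mm-unit conversions; never affects the
#'   normalized Minkowski functionals.
#' @param tumour_id opaque label for the tumour.
#' @param label optional outcome label, `"progression"` or
#'   `"pseudoprogression"`.
#' @return an object of class `"tumour_image"`.
#' @export
#' @examples
#' img <- tumour_image(matrix(1:9, 3, 3), matrix(1, 3, 3), tumour_id = "t1")
#' n_slices(img)
tumour_image <- function(slices, roi, reference = NULL, spacing = NULL,
                         tumour_id = "tumour", label = NA_character_) {
  slices <- as_slice_list(slices, "slices")
  roi <- as_slice_list(roi, "roi")
  if (length(slices) != length(roi)) {
    stop("dimensional error: ", length(slices), " slices but ",
         length(roi), " ROI masks", call. = FALSE)
  }
  for (j in seq_along(slices)) {
    if (!identical(dim(slices[[j]]), dim(roi[[j]]))) {
      stop("dimensional error: slice ", j, " is ",
           paste(dim(slices[[j]]), collapse = "x"), " but its ROI mask is ",
           paste(dim(roi[[j]]), collapse = "x"), call. = FALSE)
    }
    if (!all(is.finite(slices[[j]]))) {
      stop("data error: non-finite intensity in slice ", j, call. = FALSE)
    }
    if (any(slices[[j]] < 0)) {
      stop("data error: negative intensity in slice ", j, call. = FALSE)
    }
    roi[[j]] <- check_binary_mask(roi[[j]], paste0("roi slice ", j))
  }
  if (sum(vapply(roi, sum, numeric(1))) == 0) {
    stop("empty-mask error: ROI contains no pixels on any slice",
         call. = FALSE)
  }
  if (!is.null(reference)) {
    if (is.matrix(reference)) {
      ref <- vector("list", length(slices))
      for (j in seq_along(ref)) ref[[j]] <- array(0, dim(slices[[j]]))
      ref[[1]] <- reference
      reference <- ref
    }
    reference <- as_slice_list(reference, "reference")
    if (length(reference) != length(slices)) {
      stop("dimensional error: reference mask slice count mismatch",
           call. = FALSE)
    }
    for (j in seq_along(reference)) {
      if (!identical(dim(reference[[j]]), dim(slices[[j]]))) {
        stop("dimensional error: reference mask slice ", j,
             " shape mismatch", call. = FALSE)
      }
      reference[[j]] <- check_binary_mask(reference[[j]],
                                          paste0("reference slice ", j))
    }
  }
  if (!is.na(label) && !label %in% c("progression", "pseudoprogression")) {
    stop("label must be 'progression' or 'pseudoprogression'", call. = FALSE)
  }
  structure(
    list(slices = slices, roi = roi, reference = reference,
         spacing = spacing, tumour_id = as.character(tumour_id),
         label = label),
    class = "tumour_image"
  )
}

as_slice_list <- function(x, what) {
  if (is.matrix(x)) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- lapply(seq_len(dim(x)[3]), function(k) x[, , k])
  }
  if (!is.list(x) || !all(vapply(x, is.matrix, logical(1)))) {
    stop("data error: ", what, " must be a matrix, 3D array or list of ",
         "matrices", call. = FALSE)
  }
  lapply(x, function(m) {
    storage.mode(m) <- "double"
    m
  })
}

check_binary_mask <- function(m, what) {
  if (is.logical(m)) {
    mm <- array(as.double(m), dim(m))
    return(mm)
  }
  if (!all(m %in% c(0, 1))) {
    stop("data error: ", what, " contains values other than 0/1",
         call. = FALSE)
  }
  m
}

#' @export
print.tumour_image <- function(x, ...) {
  cat("<tumour_image> id:", x$tumour_id,
      if (!is.na(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  slices:", length(x$slices), "of",
      paste(dim(x$slices[[1]]), collapse = "x"),
      "| ROI pixels:", roi_pixel_count(x),
      "| reference:", if (is.null(x$reference)) "none" else "present", "\n")
  invisible(x)
}

#' Number of slices in a tumour image
#' @param img a `tumour_image`.
#' @return integer slice count.
#' @export
n_slices <- function(img) length(img$slices)

roi_pixel_count <- function(img) {
  sum(vapply(img$roi, sum, numeric(1)))
}

#' Load a tumour image from disk
#'
#' Reads a grey-scale volume together with its ROI mask (and optionally a
#' reference mask) from NIfTI files (`.nii` / `.nii.gz`) or from directories
#' of plain-text 2D numeric matrices, one file per slice. A directory may
#' contain a `sidecar.json` with fields `slices` (file names in acquisition
#' order) and `spacing`; without it, files are taken in lexicographic order.
#'
#' @param volume_path path to the grey-scale volume.
#' @param roi_path path to the binary ROI mask (same shape as the volume).
#' @param reference_path optional path to a binary reference mask.
#' @param tumour_id label for the tumour; defaults to the volume file name.
#' @param label optional outcome label.
#' @return a validated [tumour_image()].
#' @export
load_image <- function(volume_path, roi_path, reference_path = NULL,
                       tumour_id = NULL, label = NA_character_) {
  vol <- read_volume(volume_path)
  roi <- read_volume(roi_path)
  ref <- if (!is.null(reference_path)) read_volume(reference_path)$slices
  if (is.null(tumour_id)) {
    tumour_id <- sub("\\.nii(\\.gz)?$", "", basename(volume_path))
  }
  spacing <- vol$spacing
  if (is.null(spacing)) spacing <- roi$spacing
  tumour_image(vol$slices, roi$slices, reference = ref, spacing = spacing,
               tumour_id = tumour_id, label = label)
}

read_volume <- function(path) {
  if (dir.exists(path)) {
    sidecar <- file.path(path, "sidecar.json")
    spacing <- NULL
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      files <- file.path(path, meta$slices)
      spacing <- meta$spacing
    } else {
      files <- sort(list.files(path, pattern = "\\.(txt|csv|tsv|mat)$",
                               full.names = TRUE))
    }
    if (length(files) == 0) {
      stop("data error: no slice files found in ", path, call. = FALSE)
    }
    slices <- lapply(files, function(f) {
      as.matrix(utils::read.table(f, header = FALSE,
                                  sep = if (grepl("\\.csv$", f)) "," else ""))
    })
    slices <- lapply(slices, function(m) {
      dimnames(m) <- NULL
      m
    })
    return(list(slices = slices, spacing = spacing))
  }
  if (!file.exists(path)) {
    stop("data error: file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    a <- RNifti::readNifti(path)
    pix <- tryCatch(RNifti::pixdim(a), error = function(e) NULL)
    arr <- as.array(a)
    spacing <- if (!is.null(pix) && length(pix) >= 3) {
      list(pixel = pix[1:2], thickness = pix[3], gap = 0)
    }
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    return(list(slices = as_slice_list(arr, path), spacing = spacing))
  }
  # single plain-text matrix
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  list(slices = list(m), spacing = NULL)
}

#' Normalize ROI intensities onto the unit grey scale
#'
#' Maps the intensities of all ROI pixels of the tumour linearly onto
#' \[0, 1\] using a single tumour-wide minimum and maximum, so that the same
#' grey-scale thresholds are comparable across slices. A constant-intensity
#' ROI maps to all ones (every pixel white at every threshold).
#'
#' @param img a [tumour_image()].
#' @return an object of class `"normalized_roi"` with elements `slices`
#'   (matrices of normalized values, `NA` outside the ROI), `roi`, `lo`,
#'   `hi`, `n_pixels_per_slice` and `n_pixels_total`.
#' @export
normalize_roi <- function(img) {
  stopifnot(inherits(img, "tumour_image"))
  vals <- mapply(function(s, m) s[m == 1], img$slices, img$roi,
                 SIMPLIFY = FALSE)
  n_per <- vapply(vals, length, integer(1))
  if (sum(n_per) == 0) {
    stop("empty-mask error: ROI contains no pixels", call. = FALSE)
  }
  all_vals <- unlist(vals)
  lo <- min(all_vals)
  hi <- max(all_vals)
  norm_slices <- mapply(function(s, m) {
    out <- array(NA_real_, dim(s))
    inside <- m == 1
    out[inside] <- if (hi == lo) 1 else (s[inside] - lo) / (hi - lo)
    out
  }, img$slices, img$roi, SIMPLIFY = FALSE)
  structure(
    list(slices = norm_slices, roi = img$roi, lo = lo, hi = hi,
         n_pixels_per_slice = n_per, n_pixels_total = sum(n_per)),
    class = "normalized_roi"
  )
}

#' Per-slice normalized ROI intensity values
#' @param norm a `normalized_roi`.
#' @return list of numeric vectors, one per slice.
#' @export
roi_values <- function(norm) {
  stopifnot(inherits(norm, "normalized_roi"))
  mapply(function(s, m) s[m == 1], norm$slices, norm$roi, SIMPLIFY = FALSE)
}

#' Mean intensity of the reference region
#'
#' Arithmetic mean of the raw intensities under the reference
#' (contralateral white matter) mask, pooled over slices. Used as the
#' denominator of the signal-intensity features. An explicit positive scalar
#' may be passed instead of an image and is returned unchanged.
#'
#' @param img a [tumour_image()] carrying a reference mask, or a positive
#'   scalar reference mean.
#' @return positive scalar mean reference intensity.
#' @export
reference_mean <- function(img) {
  if (is.numeric(img) && length(img) == 1) {
    if (!is.finite(img) || img <= 0) {
      stop("parameter error: explicit reference mean must be a positive ",
           "finite scalar", call. = FALSE)
    }
    return(as.numeric(img))
  }
  stopifnot(inherits(img, "tumour_image"))
  if (is.null(img$reference)) {
    stop("configuration error: no reference mask present; supply a ",
         "reference mask or an explicit scalar reference mean",
         call. = FALSE)
  }
  vals <- unlist(mapply(function(s, m) s[m == 1], img$slices, img$reference,
                        SIMPLIFY = FALSE))
  if (length(vals) == 0) {
    stop("empty-mask error: reference mask contains no pixels",
         call. = FALSE)
  }
  mean(vals)
}
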