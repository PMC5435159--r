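#' Grey-scale threshold ladder
#'
#' Evenly spaced thresholds `t_i = (i - 1) / n_levels`, `i = 1..n_levels`,
#' on the normalized \[0, 1\] grey scale. The first threshold is 0 so every
#' ROI pixel is white in the first binary image; the endpoint 1 is not used,
#' so the last binary image is generically non-empty. The default of 11
#' levels gives ten equal steps from the all-white image.
#'
#' @param n_levels number of thresholds (>= 2); default 11.
#' @return strictly increasing numeric vector of length `n_levels`,
#'   starting at 0.
#' @export
#' @examples
#' threshold_sequence()     # 0, 1/11, ..., 10/11
#' threshold_sequence(2)    # 0, 0.5
threshold_sequence <- function(n_levels = 11) {
  if (!is.numeric(n_levels) || length(n_levels) != 1 || n_levels < 2 ||
      n_levels != round(n_levels)) {
    stop("parameter error: n_levels must be an integer >= 2", call. = FALSE)
  }
  (seq_len(n_levels) - 1) / n_levels
}

#' Binarize one slice of a normalized ROI
#'
#' A ROI pixel is white iff its normalized intensity is at or above the
#' threshold (ties go white, so threshold 0 makes the whole ROI white).
#' Pixels outside the ROI are excluded entirely: they are neither black nor
#' white and contribute to no cell counts, so the functionals describe the
#' segmented region only.
#'
#' @param norm a `normalized_roi` from [normalize_roi()].
#' @param slice_index slice to binarize.
#' @param t threshold in \[0, 1\].
#' @return logical matrix of white pixels (same shape as the slice). A slice
#'   with no ROI pixels yields an all-`FALSE` matrix, not an error.
#' @export
binarize <- function(norm, slice_index, t) {
  stopifnot(inherits(norm, "normalized_roi"))
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1) {
    stop("parameter error: threshold must lie in [0, 1]", call. = FALSE)
  }
  s <- norm$slices[[slice_index]]
  white <- !is.na(s) & s >= t
  white
}

#' Count faces, edges and vertices of a binary pixel pattern
#'
#' Treats each white pixel as a closed unit square and counts the distinct
#' cells of their union: `p` faces (pixels), `e` unit edges and `v` lattice
#' vertices, with cells shared between adjacent pixels counted once. These
#' counts feed the 2D Minkowski functionals via [minkowski_2d()].
#'
#' @param white logical or 0/1 matrix; `TRUE`/1 marks a white pixel.
#' @return named integer vector `c(p, e, v)`; all zero for an empty pattern.
#' @export
#' @examples
#' count_cells(matrix(1, 1, 1))  # single pixel: p=1, e=4, v=4
count_cells <- function(white) {
  w <- matrix(as.logical(white), nrow(white), ncol(white))
  p <- sum(w)
  if (p == 0) return(c(p = 0L, e = 0L, v = 0L))
  nr <- nrow(w)
  nc <- ncol(w)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- w
  # horizontal edges live on an (nr+1) x nc grid: present when the pixel
  # above or below is white; vertical edges analogously on nr x (nc+1)
  hor <- pad[1:(nr + 1L), 2:(nc + 1L), drop = FALSE] |
    pad[2:(nr + 2L), 2:(nc + 1L), drop = FALSE]
  ver <- pad[2:(nr + 1L), 1:(nc + 1L), drop = FALSE] |
    pad[2:(nr + 1L), 2:(nc + 2L), drop = FALSE]
  # lattice vertices on (nr+1) x (nc+1): present when any of the four
  # incident pixels is white
  vtx <- pad[1:(nr + 1L), 1:(nc + 1L), drop = FALSE] |
    pad[1:(nr + 1L), 2:(nc + 2L), drop = FALSE] |
    pad[2:(nr + 2L), 1:(nc + 1L), drop = FALSE] |
    pad[2:(nr + 2L), 2:(nc + 2L), drop = FALSE]
  c(p = as.integer(p), e = as.integer(sum(hor) + sum(ver)),
    v = as.integer(sum(vtx)))
}

#' 2D Minkowski functionals from cell counts
#'
#' Area `A = p`, perimeter `U = -4p + 2e` (the total black/white boundary
#' length in pixel-edge units) and genus `chi = p - e + v` (the Euler
#' characteristic: number of connected white regions, with diagonal
#' neighbours connected, minus the number of completely enclosed black
#' regions).
#'
#' @param p,e,v face, edge and vertex counts from [count_cells()].
#' @return named numeric vector `c(A, U, chi)`.
#' @export
#' @examples
#' minkowski_2d(1, 4, 4)    # unit pixel: A=1, U=4, chi=1
#' minkowski_2d(8, 24, 16)  # 3x3 ring:  A=8, U=16, chi=0
minkowski_2d <- function(p, e, v) {
  c(A = as.numeric(p), U = -4 * as.numeric(p) + 2 * as.numeric(e),
    chi = as.numeric(p) - as.numeric(e) + as.numeric(v))
}

#' Minkowski-functional threshold spectrum of a tumour
#'
#' For each grey-scale threshold, the white-pixel cell counts `(p, e, v)`
#' are summed over all slices, converted to the three Minkowski functionals
#' and divided by the total number of ROI pixels of the tumour. Normalized
#' area is reported for thresholds 2..n only, because at threshold 1 every
#' ROI pixel is white and the normalized area is identically 1; normalized
#' perimeter and genus are reported at every threshold. With the default 11
#' thresholds this gives the 32 Minkowski-functional features.
#'
#' @param norm a `normalized_roi`.
#' @param thresholds threshold ladder from [threshold_sequence()].
#' @return an object of class `"mf_spectrum"`: a list with
#'   `n_pixels_total`, named vectors `nArea`, `nPeri`, `nGenus`, the raw
#'   per-threshold count matrix `counts`, and `thresholds`.
#' @export
mf_spectrum <- function(norm, thresholds = threshold_sequence()) {
  stopifnot(inherits(norm, "normalized_roi"))
  if (any(diff(thresholds) <= 0)) {
    stop("parameter error: thresholds must be strictly increasing",
         call. = FALSE)
  }
  n_t <- length(thresholds)
  counts <- matrix(0, n_t, 3, dimnames = list(NULL, c("p", "e", "v")))
  for (j in seq_along(norm$slices)) {
    s <- norm$slices[[j]]
    for (i in seq_len(n_t)) {
      white <- !is.na(s) & s >= thresholds[i]
      counts[i, ] <- counts[i, ] + count_cells(white)
    }
  }
  n_tot <- norm$n_pixels_total
  A <- counts[, "p"]
  U <- -4 * counts[, "p"] + 2 * counts[, "e"]
  chi <- counts[, "p"] - counts[, "e"] + counts[, "v"]
  nArea <- (A / n_tot)[-1]
  names(nArea) <- paste0("nArea_", seq_len(n_t)[-1])
  nPeri <- U / n_tot
  names(nPeri) <- paste0("nPeri_", seq_len(n_t))
  nGenus <- chi / n_tot
  names(nGenus) <- paste0("nGenus_", seq_len(n_t))
  structure(
    list(n_pixels_total = n_tot, nArea = nArea, nPeri = nPeri,
         nGenus = nGenus, counts = counts, thresholds = thresholds),
    class = "mf_spectrum"
  )
}

#' @export
print.mf_spectrum <- function(x, ...) {
  cat("<mf_spectrum>", length(x$thresholds), "thresholds,",
      x$n_pixels_total, "ROI pixels\n")
  cat("  nPeri range:", signif(range(x$nPeri), 4), "\n")
  cat("  nGenus range:", signif(range(x$nGenus), 4), "\n")
  invisible(x)
}

#' Flatten a spectrum into its 32 named feature values
#' @param x an `mf_spectrum`.
#' @return named numeric vector (nArea_2..n, nPeri_1..n, nGenus_1..n).
#' @export
spectrum_values <- function(x) {
  stopifnot(inherits(x, "mf_spectrum"))
  c(x$nArea, x$nPeri, x$nGenus)
}
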