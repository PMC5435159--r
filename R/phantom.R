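#' Specification of a synthetic tumour phantom
#'
#' Parameterizes the morphological axes along which progressing and
#' pseudoprogressing lesions differ on T2-weighted images: overall size,
#' boundary irregularity (contour length per unit area), intra-lesion
#' texture heterogeneity and the depth/frequency of dark (hypointense)
#' foci that lower the minimum signal intensity.
#'
#' @param label `"progression"` or `"pseudoprogression"`.
#' @param n_slices number of slices (default 4).
#' @param base_radius lesion radius in pixels on the central slice (>= 3).
#' @param frond_amplitude relative amplitude of the boundary modulation,
#'   in \[0, 1); 0 gives a disc, larger values give frond-like margins
#'   while keeping the contour simple.
#' @param frond_modes highest angular mode of the boundary modulation.
#' @param texture_sigma standard deviation of the intra-lesion texture,
#'   as a fraction of the lesion's base intensity.
#' @param texture_corr_len correlation length of the texture field
#'   (pixels); shorter means finer-grained heterogeneity.
#' @param dark_focus_rate expected dark foci per 100 ROI pixels (Poisson).
#' @param dark_focus_depth relative intensity drop at a focus centre,
#'   in \[0, 1\].
#' @param wm_mean mean intensity of the reference white-matter region.
#' @param seed integer RNG seed; phantoms are bit-reproducible from
#'   `(spec, seed)`.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(label = c("progression", "pseudoprogression"),
                         n_slices = 4, base_radius = 12,
                         frond_amplitude = 0.2, frond_modes = 6,
                         texture_sigma = 0.15, texture_corr_len = 2,
                         dark_focus_rate = 0.5, dark_focus_depth = 0.5,
                         wm_mean = 100, seed = 1) {
  label <- match.arg(label)
  if (base_radius < 3) {
    stop("parameter error: base_radius must be >= 3", call. = FALSE)
  }
  if (frond_amplitude < 0 || frond_amplitude >= 1) {
    stop("parameter error: frond_amplitude must lie in [0, 1)",
         call. = FALSE)
  }
  if (n_slices < 1 || texture_sigma < 0 || texture_corr_len <= 0 ||
      dark_focus_rate < 0 || dark_focus_depth < 0 || dark_focus_depth > 1 ||
      wm_mean <= 0) {
    stop("parameter error: invalid phantom specification", call. = FALSE)
  }
  structure(
    list(label = label, n_slices = n_slices, base_radius = base_radius,
         frond_amplitude = frond_amplitude, frond_modes = frond_modes,
         texture_sigma = texture_sigma, texture_corr_len = texture_corr_len,
         dark_focus_rate = dark_focus_rate,
         dark_focus_depth = dark_focus_depth, wm_mean = wm_mean,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default class specifications for a phantom cohort
#'
#' Encode the phenotype contrast of the two outcome classes: progressing
#' lesions are larger, more frond-like (longer contour per unit area),
#' more finely textured, and carry more and deeper dark foci (hence a
#' lower minimum signal intensity); pseudoprogressing lesions are the
#' converse. Both appear T2-hyperintense relative to the white-matter
#' reference.
#'
#' @param seed base seed stored in the spec (overridden per phantom by
#'   [make_cohort()]).
#' @return a `phantom_spec`.
#' @export
default_progression_spec <- function(seed = 1) {
  phantom_spec("progression", n_slices = 4, base_radius = 16,
               frond_amplitude = 0.55, frond_modes = 12,
               texture_sigma = 0.25, texture_corr_len = 1.5,
               dark_focus_rate = 1.2, dark_focus_depth = 0.7,
               wm_mean = 100, seed = seed)
}

#' @rdname default_progression_spec
#' @export
default_pseudoprogression_spec <- function(seed = 1) {
  phantom_spec("pseudoprogression", n_slices = 4, base_radius = 11,
               frond_amplitude = 0.10, frond_modes = 4,
               texture_sigma = 0.12, texture_corr_len = 3,
               dark_focus_rate = 0.3, dark_focus_depth = 0.4,
               wm_mean = 100, seed = seed)
}

# separable Gaussian smoothing with reflected edges; sigma in pixels
gaussian_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(v) {
    padded <- c(rev(v[seq_len(half)]), v,
                rev(v[(length(v) - half + 1):length(v)]))
    stats::filter(padded, k, sides = 2)[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(t(m), 2, smooth_1d))
}

#' Generate one synthetic tumour phantom
#'
#' Builds a multi-slice [tumour_image()] from a [phantom_spec()]. Per
#' slice, the ROI boundary is `r(theta) = R_j (1 + a sum_m a_m cos(m theta
#' + phi_m))` with random mode weights normalized so the total modulation
#' never exceeds `frond_amplitude`; slice radii `R_j` follow a spherical
#' cap profile. Interior intensity is a hyperintense base level modulated
#' by a Gaussian random field (white noise smoothed with an isotropic
#' Gaussian kernel of width `texture_corr_len`, rescaled to
#' `texture_sigma`), with circular dark foci punched in at a Poisson rate.
#' A square reference region of white-matter intensity sits in the image
#' corner, away from the lesion. All randomness derives from `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return a [tumour_image()] with `label` set and the spec attached as
#'   attribute `"spec"`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  r_max <- ceiling(spec$base_radius * (1 + spec$frond_amplitude))
  G <- 2L * r_max + 28L
  centre <- G / 2 + 6
  base_level <- 1.6 * spec$wm_mean  # T2-hyperintense lesion
  xs <- matrix(rep(seq_len(G), each = G), G, G)   # column index
  ys <- matrix(rep(seq_len(G), times = G), G, G)  # row index
  dx <- xs - centre
  dy <- ys - centre
  theta <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  ref_mask <- matrix(0, G, G)
  ref_mask[3:10, 3:10] <- 1
  slices <- vector("list", spec$n_slices)
  rois <- vector("list", spec$n_slices)
  refs <- vector("list", spec$n_slices)
  u <- if (spec$n_slices == 1) 0 else {
    (seq_len(spec$n_slices) - (spec$n_slices + 1) / 2) /
      ((spec$n_slices + 1) / 2)
  }
  for (j in seq_len(spec$n_slices)) {
    R_j <- max(3, spec$base_radius * sqrt(1 - u[j]^2))
    boundary <- rep(R_j, G * G)
    if (spec$frond_amplitude > 0 && spec$frond_modes >= 1) {
      a_m <- stats::rnorm(spec$frond_modes)
      phi <- stats::runif(spec$frond_modes, 0, 2 * pi)
      mod <- 0
      for (m in seq_len(spec$frond_modes)) {
        mod <- mod + a_m[m] * cos(m * theta + phi[m])
      }
      # normalize so the modulation attains +/-1 but never exceeds it:
      # the boundary stays star-shaped and strictly positive
      mod <- mod / max(abs(mod))
      boundary <- R_j * (1 + spec$frond_amplitude * mod)
    }
    roi <- matrix(as.numeric(rho <= boundary), G, G)
    # background brain-like intensity with mild noise
    img <- spec$wm_mean * (1 + 0.02 * stats::rnorm(G * G))
    img <- matrix(img, G, G)
    # lesion: base level + Gaussian random field texture
    lesion <- matrix(base_level, G, G)
    if (spec$texture_sigma > 0) {
      field <- gaussian_smooth(matrix(stats::rnorm(G * G), G, G),
                               spec$texture_corr_len)
      field <- field / stats::sd(field)
      lesion <- base_level * (1 + spec$texture_sigma * field)
    }
    # dark foci (microhaemorrhage / necrosis-like intensity depressions)
    n_roi <- sum(roi)
    n_foci <- stats::rpois(1, spec$dark_focus_rate * n_roi / 100)
    if (n_foci > 0 && spec$dark_focus_depth > 0) {
      idx <- which(roi == 1)
      pick <- sample(idx, n_foci, replace = TRUE)
      for (ctr in pick) {
        ci <- ((ctr - 1) %% G) + 1
        cj <- ((ctr - 1) %/% G) + 1
        rad <- stats::runif(1, 1.5, 3)
        d2 <- (ys - ci)^2 + (xs - cj)^2
        lesion <- lesion * (1 - spec$dark_focus_depth * exp(-d2 / rad^2))
      }
    }
    img[roi == 1] <- lesion[roi == 1]
    img[ref_mask == 1] <- spec$wm_mean * (1 + 0.02 *
                                            stats::rnorm(sum(ref_mask)))
    img <- pmax(img, 0)
    slices[[j]] <- img
    rois[[j]] <- roi
    refs[[j]] <- ref_mask
  }
  out <- tumour_image(slices, rois, reference = refs,
                      spacing = list(pixel = c(1, 1), thickness = 1,
                                     gap = 0),
                      tumour_id = sprintf("%s_seed%d",
                                          substr(spec$label, 1, 4),
                                          spec$seed),
                      label = spec$label)
  attr(out, "spec") <- spec
  out
}

#' Generate a labelled two-class phantom cohort
#'
#' Produces `n_per_class` phantoms per outcome class from the two class
#' specifications, with per-phantom seeds derived deterministically from
#' the cohort seed, so the whole cohort is bit-reproducible.
#'
#' @param n_per_class phantoms per class (>= 2).
#' @param progression_spec,pseudo_spec class specifications; defaults
#'   [default_progression_spec()] / [default_pseudoprogression_spec()].
#' @param seed cohort seed.
#' @return an object of class `"labelled_cohort"`: list with `images`,
#'   `labels`, `specs`, `seed`.
#' @export
make_cohort <- function(n_per_class = 10,
                        progression_spec = default_progression_spec(),
                        pseudo_spec = default_pseudoprogression_spec(),
                        seed = 1) {
  if (n_per_class < 2) {
    stop("parameter error: n_per_class must be >= 2", call. = FALSE)
  }
  specs <- vector("list", 2 * n_per_class)
  images <- vector("list", 2 * n_per_class)
  base <- list(progression_spec, pseudo_spec)
  for (i in seq_len(2 * n_per_class)) {
    cls <- if (i <= n_per_class) 1 else 2
    sp <- base[[cls]]
    sp$seed <- as.integer(seed + 7919L * i)  # distinct per-phantom seeds
    img <- make_phantom(sp)
    img$tumour_id <- sprintf("%s_%02d", substr(sp$label, 1, 6),
                             ((i - 1) %% n_per_class) + 1)
    specs[[i]] <- sp
    images[[i]] <- img
  }
  structure(
    list(images = images,
         labels = vapply(images, function(im) im$label, character(1)),
         specs = specs, seed = as.integer(seed)),
    class = "labelled_cohort"
  )
}

#' @export
print.labelled_cohort <- function(x, ...) {
  cat("<labelled_cohort>", length(x$images), "phantoms (",
      paste(sprintf("%s: %d", names(table(x$labels)), table(x$labels)),
            collapse = ", "), "), seed", x$seed, "\n")
  invisible(x)
}

#' Sphere reference curve: expected perimeter for a given total area
#'
#' For a tumour summarized by its summed cross-sectional area over slices,
#' returns the summed perimeter that a sphere of matching summed
#' cross-section would have when sliced at the given spacing: the stack of
#' circular discs with radii `sqrt(R^2 - z_k^2)` at slice centres `z_k =
#' +/- s(k - 1/2)`. Real lesions with irregular, frond-like margins lie
#' above this curve (more contour per unit area). Perimeters are
#' geometric (`2 pi r`); rasterized contours measured in pixel-edge units
#' exceed them by up to a factor 4/pi.
#'
#' @param total_area summed cross-sectional area (pixel^2 or mm^2).
#' @param slice_spacing slice thickness plus gap, in the same length unit
#'   (default 1).
#' @return expected total perimeter (same length unit).
#' @export
sphere_reference <- function(total_area, slice_spacing = 1) {
  if (!is.numeric(total_area) || any(total_area <= 0)) {
    stop("parameter error: total_area must be positive", call. = FALSE)
  }
  if (slice_spacing <= 0) {
    stop("parameter error: slice_spacing must be positive", call. = FALSE)
  }
  s <- slice_spacing
  disc_sum <- function(R, f) {
    k <- seq_len(max(1, ceiling(R / s)))
    z <- s * (k - 0.5)
    z <- z[z < R]
    if (length(z) == 0) return(0)
    2 * sum(f(sqrt(R^2 - z^2)))
  }
  vapply(total_area, function(ta) {
    f_area <- function(R) disc_sum(R, function(r) pi * r^2) - ta
    hi <- (3 * s * ta / (4 * pi))^(1 / 3) * 2 + 2 * s
    while (f_area(hi) < 0) hi <- hi * 2
    R <- stats::uniroot(f_area, c(1e-9, hi), tol = 1e-10)$root
    disc_sum(R, function(r) 2 * pi * r)
  }, numeric(1))
}
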