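# small in-code fixtures shared across test files

# deterministic 2-slice tumour with an 8x8 ROI and a reference block
tiny_image <- function() {
  set.seed(42)
  s1 <- matrix(runif(144, 50, 150), 12, 12)
  s2 <- matrix(runif(144, 50, 150), 12, 12)
  roi <- matrix(0, 12, 12)
  roi[3:10, 3:10] <- 1
  ref <- matrix(0, 12, 12)
  ref[1:2, 1:2] <- 1
  tumour_image(list(s1, s2), list(roi, roi), reference = list(ref, ref),
               tumour_id = "tiny")
}

# fast phantoms for unit tests (small radius, 2 slices)
small_prog_spec <- function(seed = 1) {
  phantom_spec("progression", n_slices = 2, base_radius = 9,
               frond_amplitude = 0.45, frond_modes = 8,
               texture_sigma = 0.25, texture_corr_len = 1.5,
               dark_focus_rate = 1.2, dark_focus_depth = 0.7, seed = seed)
}

small_pseudo_spec <- function(seed = 1) {
  phantom_spec("pseudoprogression", n_slices = 2, base_radius = 7,
               frond_amplitude = 0.1, frond_modes = 4,
               texture_sigma = 0.12, texture_corr_len = 3,
               dark_focus_rate = 0.3, dark_focus_depth = 0.4, seed = seed)
}

# two well-separated gaussian clouds in 2 features
separable_toy <- function(n_per_class = 10, seed = 1, gap = 6) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class) + gap, ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c("pseudoprogression", "progression"),
                      each = n_per_class))
}

# labelled feature table with one informative feature among noise
noise_table <- function(n_per_class = 20, n_noise = 9, effect = 3,
                        seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c("pseudoprogression", "progression"), each = n_per_class)
  df <- data.frame(tumour_id = sprintf("t%02d", seq_len(n)), label = lab,
                   stringsAsFactors = FALSE)
  df$informative <- rnorm(n) + effect * (lab == "progression")
  for (k in seq_len(n_noise)) df[[paste0("noise", k)]] <- rnorm(n)
  df
}
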