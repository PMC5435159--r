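test_that("phantom specs validate their invariants", {
  expect_error(phantom_spec(base_radius = 2), "base_radius")
  expect_error(phantom_spec(frond_amplitude = 1), "frond_amplitude")
  expect_error(phantom_spec(dark_focus_rate = -1), "invalid")
  expect_error(phantom_spec(wm_mean = 0), "invalid")
})

test_that("phantoms are bit-reproducible from (spec, seed)", {
  sp <- small_prog_spec(seed = 13)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$slices, b$slices)
  expect_identical(a$roi, b$roi)
  co1 <- make_cohort(2, small_prog_spec(), small_pseudo_spec(), seed = 5)
  co2 <- make_cohort(2, small_prog_spec(), small_pseudo_spec(), seed = 5)
  expect_identical(lapply(co1$images, `[[`, "slices"),
                   lapply(co2$images, `[[`, "slices"))
})

test_that("a smooth disc phantom matches the rasterized-circle oracle", {
  sp <- phantom_spec("pseudoprogression", n_slices = 1, base_radius = 10,
                     frond_amplitude = 0, texture_sigma = 0,
                     dark_focus_rate = 0, seed = 2)
  img <- make_phantom(sp)
  sz <- size_features(img)
  # independent rasterization of the same disc on a fresh grid
  G <- 41
  ctr <- 21
  disc <- outer(seq_len(G), seq_len(G),
                function(i, j) sqrt((i - ctr)^2 + (j - ctr)^2) <= 10)
  expect_equal(unname(sz["TotalArea"]), sum(disc), tolerance = 0.02)
  expect_equal(unname(sz["TotalPerimeter"]),
               as.numeric(oracle_perimeter(disc)), tolerance = 0.1)
  # constant intensity inside the ROI
  vals <- img$slices[[1]][img$roi[[1]] == 1]
  expect_equal(sd(vals), 0)
})

test_that("boundary fronds lengthen the contour at fixed radius", {
  for (seed in 1:20) {
    sp0 <- phantom_spec("progression", n_slices = 1, base_radius = 10,
                        frond_amplitude = 0, texture_sigma = 0,
                        dark_focus_rate = 0, seed = seed)
    sp4 <- sp0
    sp4$frond_amplitude <- 0.4
    sp4$frond_modes <- 8
    tp0 <- size_features(make_phantom(sp0))["TotalPerimeter"]
    tp4 <- size_features(make_phantom(sp4))["TotalPerimeter"]
    expect_gt(tp4, tp0)
  }
})

test_that("cohorts carry the phenotype contrast of the two classes", {
  co <- make_cohort(10, seed = 3)
  expect_length(co$images, 20)
  expect_equal(unname(table(co$labels)["progression"]), 10)
  ta <- sapply(co$images, function(im) size_features(im)["TotalArea"])
  si_min <- sapply(co$images, function(im) {
    min(unlist(mapply(function(s, m) s[m == 1], im$slices, im$roi))) /
      reference_mean(im)
  })
  prog <- co$labels == "progression"
  expect_gt(mean(ta[prog]), mean(ta[!prog]))
  expect_lt(mean(si_min[prog]), mean(si_min[!prog]))
})

test_that("mid-threshold perimeter of progression phantoms dominates", {
  co <- make_cohort(12, seed = 9)
  mid_peri <- sapply(co$images, function(im) {
    sp <- mf_spectrum(normalize_roi(im))
    mean(sp$nPeri[paste0("nPeri_", 5:7)])
  })
  prog <- co$labels == "progression"
  w <- wilcox.test(mid_peri[prog], mid_peri[!prog],
                   alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("sphere reference reproduces disc-stack geometry", {
  # quadrature / closed-form oracle: summed disc area ~ (4/3) pi R^3 / s,
  # summed circumference ~ pi^2 R^2 / s for fine slicing
  R <- 30
  s <- 0.25
  k <- seq_len(ceiling(R / s))
  z <- s * (k - 0.5)
  z <- z[z < R]
  ta <- 2 * sum(pi * (R^2 - z^2))
  expect_equal(sphere_reference(ta, s), pi^2 * R^2 / s, tolerance = 0.01)

  # sub-linear (sphere-like) scaling
  tp1 <- sphere_reference(2000, 1)
  tp2 <- sphere_reference(4000, 1)
  expect_lt(tp2, 2 * tp1)
  expect_gt(tp2, tp1)

  # single-slice isoperimetric check: any rasterized lesion has at least
  # the contour of the equal-area circle
  img <- make_phantom(small_pseudo_spec(seed = 4))
  sz <- size_features(img)
  expect_gte(sz["TotalPerimeter"], 2 * sqrt(pi * sz["TotalArea"] / 2) * 2)

  expect_error(sphere_reference(-5), "positive")
  expect_error(sphere_reference(10, 0), "positive")
})
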