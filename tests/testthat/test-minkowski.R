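test_that("threshold ladder is an even partition of the unit grey scale", {
  t11 <- threshold_sequence()
  expect_length(t11, 11)
  expect_equal(t11[1], 0)
  expect_equal(t11[11], 10 / 11)
  expect_true(all(diff(t11) > 0))
  expect_equal(threshold_sequence(2), c(0, 0.5))
  expect_error(threshold_sequence(1), "parameter error")
})

test_that("binarization uses the at-or-above rule on ROI pixels only", {
  s <- matrix(0, 1, 3)
  s[1, ] <- c(0, 0.5, 1.0) * 100
  roi <- matrix(1, 1, 3)
  norm <- normalize_roi(tumour_image(s, roi))
  expect_equal(sum(binarize(norm, 1, 0)), 3)    # threshold 1: all white
  expect_equal(sum(binarize(norm, 1, 0.6)), 1)  # only the 1.0 pixel
  # a pixel at the maximum is white at every threshold
  for (t in threshold_sequence()) {
    expect_true(binarize(norm, 1, t)[1, 3])
  }
  # tie goes white
  norm_tie <- normalize_roi(tumour_image(matrix(c(0, 0.5, 1), 1, 3),
                                         matrix(1, 1, 3)))
  expect_true(binarize(norm_tie, 1, 0.5)[1, 2])
  # pixels outside the ROI are excluded, not black
  roi2 <- matrix(c(1, 0, 1), 1, 3)
  norm2 <- normalize_roi(tumour_image(s, roi2))
  expect_equal(unname(count_cells(binarize(norm2, 1, 0))["p"]), 2L)
  expect_error(binarize(norm, 1, 1.5), "parameter error")
})

worked_patterns <- function() {
  ring <- matrix(1, 3, 3)
  ring[2, 2] <- 0
  list(
    pixel = list(m = matrix(1, 1, 1), pev = c(1, 4, 4), mf = c(1, 4, 1)),
    block = list(m = matrix(1, 2, 2), pev = c(4, 12, 9), mf = c(4, 8, 1)),
    diag = list(m = matrix(c(1, 0, 0, 1), 2, 2), pev = c(2, 8, 7),
                mf = c(2, 8, 1)),
    ring = list(m = ring, pev = c(8, 24, 16), mf = c(8, 16, 0))
  )
}

test_that("worked cell counts and functionals match exact enumeration", {
  for (nm in names(worked_patterns())) {
    case <- worked_patterns()[[nm]]
    got <- count_cells(case$m)
    expect_equal(unname(got), case$pev, info = nm)
    expect_equal(unname(oracle_pev(case$m)), case$pev, info = nm)
    mf <- minkowski_2d(got["p"], got["e"], got["v"])
    expect_equal(unname(mf), case$mf, info = nm)
  }
  expect_equal(unname(count_cells(matrix(0, 4, 4))), c(0L, 0L, 0L))
})

test_that("cell counts obey combinatorial bounds and slice additivity", {
  set.seed(101)
  for (rep in 1:100) {
    w <- random_binary(sample(1:10, 1), sample(1:10, 1),
                       prob = runif(1, 0.1, 0.9))
    cc <- count_cells(w)
    expect_equal(unname(cc), unname(oracle_pev(w)))
    if (cc["p"] > 0) {
      expect_gte(cc["e"], 2 * cc["p"])
      expect_lte(cc["e"], 4 * cc["p"])
      expect_gte(cc["v"], cc["p"])
      expect_lte(cc["v"], 4 * cc["p"])
    }
  }
  # disjoint union of two patterns counts like the sum of the parts
  set.seed(7)
  a <- random_binary(5, 5)
  b <- random_binary(5, 5)
  joint <- matrix(FALSE, 5, 12)
  joint[, 1:5] <- a
  joint[, 8:12] <- b
  expect_equal(count_cells(joint), count_cells(a) + count_cells(b))
})

test_that("genus and perimeter match independent labelling and edge scans", {
  set.seed(2024)
  for (rep in 1:250) {
    w <- random_binary(sample(2:12, 1), sample(2:12, 1),
                       prob = runif(1, 0.2, 0.8))
    cc <- count_cells(w)
    mf <- minkowski_2d(cc["p"], cc["e"], cc["v"])
    expect_equal(unname(mf["chi"]), oracle_genus(w))
    expect_equal(unname(mf["U"]), as.numeric(oracle_perimeter(w)))
  }
})

test_that("the spectrum is normalized per tumour and sized per Table-style contract", {
  img <- tiny_image()
  norm <- normalize_roi(img)
  spec <- mf_spectrum(norm)
  expect_length(spectrum_values(spec), 32)
  # implied normalized area at threshold 1 is exactly 1
  expect_equal(unname(spec$counts[1, "p"]) / spec$n_pixels_total, 1)
  # normalized area is non-increasing and within [0, 1]
  nA <- c(1, unname(spec$nArea))
  expect_true(all(diff(nA) <= 0))
  expect_true(all(nA >= 0 & nA <= 1))

  # single-pixel ROI: nPeri_1 = 4, nGenus_1 = 1
  single <- tumour_image(matrix(5, 3, 3),
                         {
                           m <- matrix(0, 3, 3)
                           m[2, 2] <- 1
                           m
                         })
  sp1 <- mf_spectrum(normalize_roi(single))
  expect_equal(unname(sp1$nPeri["nPeri_1"]), 4)
  expect_equal(unname(sp1$nGenus["nGenus_1"]), 1)

  # two slices each a uniform 2x2 block: counts sum over slices, nPeri = 2
  blk <- matrix(0, 4, 4)
  blk[2:3, 2:3] <- 1
  two <- tumour_image(list(blk * 7, blk * 7), list(blk, blk))
  sp2 <- mf_spectrum(normalize_roi(two))
  expect_true(all(sp2$nPeri == 2))
  expect_equal(sp2$n_pixels_total, 8L)
})

test_that("duplicating slices preserves normalized MFs and doubles size", {
  img <- make_phantom(small_prog_spec(seed = 3))
  dup <- tumour_image(c(img$slices, img$slices), c(img$roi, img$roi),
                      reference = c(img$reference, img$reference))
  sp <- mf_spectrum(normalize_roi(img))
  sp_dup <- mf_spectrum(normalize_roi(dup))
  expect_equal(spectrum_values(sp_dup), spectrum_values(sp),
               tolerance = 1e-12)
  expect_equal(size_features(dup), 2 * size_features(img))
})

test_that("a checkerboard ROI has higher mid-threshold perimeter than a uniform one", {
  n <- 8
  vals <- matrix(100, n, n)
  checker <- (outer(1:n, 1:n, "+") %% 2 == 0) * 100 + 50
  roi <- matrix(1, n, n)
  sp_uniform <- mf_spectrum(normalize_roi(tumour_image(vals, roi)))
  sp_checker <- mf_spectrum(normalize_roi(tumour_image(checker, roi)))
  mid <- paste0("nPeri_", 5:7)
  expect_true(all(sp_checker$nPeri[mid] > sp_uniform$nPeri[mid]))
})
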