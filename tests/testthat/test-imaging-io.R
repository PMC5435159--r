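test_that("tumour_image validates shapes, mask values and intensities", {
  vol <- lapply(1:3, function(i) matrix(runif(64 * 64, 10, 100), 64, 64))
  roi <- lapply(1:3, function(i) matrix(rbinom(64 * 64, 1, 0.2), 64, 64))
  img <- tumour_image(vol, roi, tumour_id = "t")
  expect_s3_class(img, "tumour_image")
  expect_equal(n_slices(img), 3)

  bad_roi <- roi
  bad_roi[[2]] <- bad_roi[[2]][, 1:63]
  expect_error(tumour_image(vol, bad_roi), "dimensional")

  roi2 <- roi
  roi2[[1]][1, 1] <- 2
  expect_error(tumour_image(vol, roi2), "0/1")

  empty <- lapply(roi, function(m) m * 0)
  expect_error(tumour_image(vol, empty), "empty-mask")

  vol2 <- vol
  vol2[[3]][5, 5] <- NaN
  expect_error(tumour_image(vol2, roi), "non-finite")
  vol3 <- vol
  vol3[[1]][2, 2] <- -1
  expect_error(tumour_image(vol3, roi), "negative")
})

test_that("NIfTI volumes round-trip through load_image", {
  skip_if_not_installed("RNifti")
  tmp <- withr::local_tempdir()
  arr <- array(runif(16 * 16 * 3, 0, 200), c(16, 16, 3))
  mask <- array(0, c(16, 16, 3))
  mask[5:12, 5:12, ] <- 1
  vol_p <- file.path(tmp, "vol.nii.gz")
  roi_p <- file.path(tmp, "roi.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), vol_p)
  RNifti::writeNifti(RNifti::asNifti(mask), roi_p)
  img <- load_image(vol_p, roi_p)
  expect_equal(n_slices(img), 3)
  expect_equal(img$slices[[2]], arr[, , 2], tolerance = 1e-6)
  expect_equal(img$tumour_id, "vol")

  bad <- array(0, c(16, 15, 3))
  bad[5, 5, ] <- 1
  bad_p <- file.path(tmp, "bad.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(bad), bad_p)
  expect_error(load_image(vol_p, bad_p), "dimensional")
})

test_that("directories of plain-text matrices load with a JSON sidecar", {
  tmp <- withr::local_tempdir()
  vd <- file.path(tmp, "vol")
  rd <- file.path(tmp, "roi")
  dir.create(vd)
  dir.create(rd)
  m1 <- matrix(1:20, 4, 5)
  m2 <- matrix(21:40, 4, 5)
  write.table(m1, file.path(vd, "b.txt"), row.names = FALSE,
              col.names = FALSE)
  write.table(m2, file.path(vd, "a.txt"), row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(slices = c("b.txt", "a.txt")),
                       file.path(vd, "sidecar.json"), auto_unbox = TRUE)
  roi <- matrix(0, 4, 5)
  roi[2:3, 2:3] <- 1
  write.table(roi, file.path(rd, "s1.txt"), row.names = FALSE,
              col.names = FALSE)
  write.table(roi, file.path(rd, "s2.txt"), row.names = FALSE,
              col.names = FALSE)
  img <- load_image(vd, rd, tumour_id = "dircase")
  # sidecar order: b.txt first
  expect_equal(img$slices[[1]], matrix(as.double(1:20), 4, 5))
  expect_equal(img$slices[[2]], matrix(as.double(21:40), 4, 5))
})

test_that("normalize_roi maps the tumour-wide range onto [0, 1]", {
  mk <- function(vals_by_slice) {
    slices <- lapply(vals_by_slice, function(v) {
      m <- matrix(0, 2, max(lengths(vals_by_slice)))
      m[1, seq_along(v)] <- v
      m
    })
    rois <- lapply(vals_by_slice, function(v) {
      m <- matrix(0, 2, max(lengths(vals_by_slice)))
      m[1, seq_along(v)] <- 1
      m
    })
    tumour_image(slices, rois)
  }
  n1 <- normalize_roi(mk(list(c(10, 20, 30))))
  expect_equal(sort(roi_values(n1)[[1]]), c(0, 0.5, 1))

  n2 <- normalize_roi(mk(list(c(7, 7, 7))))
  expect_equal(roi_values(n2)[[1]], c(1, 1, 1))

  # tumour-wide (not per-slice) bounds
  n3 <- normalize_roi(mk(list(c(0, 4), c(8))))
  expect_equal(sort(roi_values(n3)[[1]]), c(0, 0.5))
  expect_equal(roi_values(n3)[[2]], 1)
  expect_equal(n3$n_pixels_per_slice, c(2L, 1L))
  expect_equal(n3$n_pixels_total, 3L)
})

test_that("normalization is idempotent and affine-invariant", {
  img <- tiny_image()
  n1 <- normalize_roi(img)
  # re-normalizing an already-[0,1] ROI with lo=0, hi=1 leaves it unchanged
  renorm_slices <- lapply(n1$slices, function(s) {
    s2 <- s
    s2[is.na(s2)] <- 0
    s2
  })
  img2 <- tumour_image(renorm_slices, img$roi)
  n2 <- normalize_roi(img2)
  expect_equal(roi_values(n2), roi_values(n1), tolerance = 1e-12)

  # affine intensity transform a*x + b, a > 0
  img3 <- tumour_image(lapply(img$slices, function(s) 3.7 * s + 11),
                       img$roi)
  n3 <- normalize_roi(img3)
  expect_equal(roi_values(n3), roi_values(n1), tolerance = 1e-12)

  expect_equal(n1$n_pixels_total, sum(sapply(img$roi, sum)))
})

test_that("reference_mean pools reference pixels or passes a scalar through", {
  s <- matrix(0, 2, 2)
  s[1, ] <- c(100, 120)
  roi <- matrix(c(0, 1, 0, 0), 2, 2)
  ref <- matrix(c(1, 0, 1, 0), 2, 2)
  img <- tumour_image(s, roi, reference = ref)
  expect_equal(reference_mean(img), 110)

  img_noref <- tumour_image(s, roi)
  expect_error(reference_mean(img_noref), "configuration error")
  img_empty_ref <- tumour_image(s, roi, reference = matrix(0, 2, 2))
  expect_error(reference_mean(img_empty_ref), "empty-mask")
  expect_equal(reference_mean(95), 95)
  expect_error(reference_mean(-2), "positive")
})
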