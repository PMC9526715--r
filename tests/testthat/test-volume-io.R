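test_that("CT volumes round-trip through NIfTI with voxels and spacing intact", {
  v <- ct_volume(array(rnorm(8 * 8 * 8, 50, 300), c(8, 8, 8)),
                 spacing = c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$voxels, v$voxels)
  expect_equal(v2$spacing, c(1, 1, 1))

  vph <- ct_volume(array(rnorm(6 * 10 * 12, 0, 100), c(6, 10, 12)),
                   spacing = c(1.5, 1.5, 5.0))
  write_volume(vph, f)
  expect_equal(read_volume(f)$spacing, c(1.5, 1.5, 5.0))
})

test_that("ingest clamps to the 12-bit HU range", {
  v <- ct_volume(array(c(5000, -2000, 100, rep(0, 24 - 3)), c(2, 3, 4)))
  expect_equal(max(v$voxels), 3071)
  expect_equal(min(v$voxels), -1024)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  raw <- array(0, c(4, 4, 4)); raw[1, 1, 1] <- 5000
  write_volume(ct_volume(raw, clamp = FALSE), f)
  expect_equal(max(read_volume(f)$voxels), 3071)
})

test_that("label maps round-trip exactly including the ignore value", {
  lv <- label_volume(array(0L, c(4, 4, 4)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_labelmap(lv, f)
  expect_identical(read_labelmap(f)$labels, lv$labels)

  lv2 <- random_label_volume(c(5, 6, 7), p_ignore = 0.2)
  stopifnot(setequal(unique(as.vector(lv2$labels)), c(0L, 1L, 2L, 255L)))
  write_labelmap(lv2, f)
  expect_identical(read_labelmap(f)$labels, lv2$labels)
})

test_that("reading rejects missing files and non-3D images", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "not found")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4)), f)
  expect_error(read_volume(f), "3D")
})

test_that("slice-thickness resampling preserves extent and label sets", {
  v <- ct_volume(array(rnorm(90 * 6 * 6), c(90, 6, 6)), spacing = c(1, 1, 1.5))
  out <- resample_slice_thickness(v, 5)
  expect_equal(dim(out$voxels)[1], 27)          # floor(135 / 5)
  expect_equal(out$spacing[3], 5)
  # physical extent conserved to within one output slice
  expect_lte(abs(90 * 1.5 - 27 * 5), 5)

  # identity case
  v5 <- ct_volume(array(rnorm(10 * 4 * 4), c(10, 4, 4)), spacing = c(1, 1, 5))
  expect_equal(resample_slice_thickness(v5, 5)$voxels, v5$voxels)

  lv <- label_volume(array(sample(c(0L, 1L), 90 * 6 * 6, TRUE), c(90, 6, 6)),
                     spacing = c(1, 1, 1.5))
  rl <- resample_slice_thickness(lv, 5)
  expect_true(all(unique(as.vector(rl$labels)) %in% c(0L, 1L)))
  expect_error(resample_slice_thickness(v, -1), "positive")
})

test_that("axial resampling conserves physical extent via spacing rescale", {
  v <- ct_volume(array(rnorm(4 * 64 * 64), c(4, 64, 64)),
                 spacing = c(0.75, 0.75, 5))
  out <- resample_axial(v, c(32L, 32L))
  expect_equal(dim(out$voxels), c(4L, 32L, 32L))
  expect_equal(out$spacing[1:2], c(1.5, 1.5))    # 64 * 0.75 == 32 * 1.5
  expect_equal(resample_axial(v, c(64L, 64L))$voxels, v$voxels)

  lv <- label_volume(array(sample(c(0L, 1L, 2L), 4 * 64 * 64, TRUE),
                           c(4, 64, 64)), spacing = c(0.75, 0.75, 5))
  rl <- resample_axial(lv, c(32L, 32L))
  expect_true(all(unique(as.vector(rl$labels)) %in% c(0L, 1L, 2L)))
  expect_error(resample_axial(v, c(0L, 32L)), ">= 1")
})

test_that("containers validate their invariants", {
  expect_error(ct_volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
  expect_error(label_volume(array(7L, c(2, 2, 2))), "unexpected label")
  expect_error(ct_volume(matrix(1, 2, 2)), "3D")
})
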