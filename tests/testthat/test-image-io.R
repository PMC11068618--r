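test_that("NIfTI round-trip preserves voxels and spacing", {
  set.seed(1)
  v <- volume(array(rnorm(32 * 32 * 16), c(32, 32, 16)), c(1, 1, 1), "MRI")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f, "MRI")
  expect_equal(dim(r$voxels), c(32L, 32L, 16L))
  expect_equal(r$voxels, v$voxels, tolerance = 1e-6)
  expect_lt(max(abs(r$spacing - v$spacing)), 1e-6)

  # anisotropic spacing survives
  v2 <- volume(array(runif(8 * 8 * 4), c(8, 8, 4)), fixture_spacing, "MRI")
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(v2, f2)
  expect_lt(max(abs(read_volume(f2, "MRI")$spacing - fixture_spacing)), 1e-6)

  # masks are stored as uint8 {0,1} and read back bit-exactly
  m <- binary_mask(random_mask(c(8, 8, 4)), fixture_spacing)
  fm <- tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  rm_ <- read_volume(fm, "MASK")
  expect_identical(sort(unique(as.vector(rm_$voxels))), sort(unique(as.vector(m$voxels))))
  expect_equal(rm_$voxels, m$voxels)
})

test_that("read_volume rejects missing files and non-3D images", {
  expect_error(read_volume(tempfile(), "CT"), "missing file")
  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f, "CT"), "non-3D")
})

test_that("volume constructor enforces invariants", {
  expect_error(volume(array(0, c(4, 4)), c(1, 1, 1), "CT"), "non-3D")
  expect_error(volume(array(0, c(4, 4, 4)), c(1, 0, 1), "CT"), "spacing")
  expect_error(volume(array(NA_real_, c(4, 4, 4)), c(1, 1, 1), "MRI"), "finite")
  expect_error(volume(array(5000, c(4, 4, 4)), c(1, 1, 1), "CT"), "HU range")
  bad <- array(0, c(4, 4, 4)); bad[1] <- -2
  expect_error(volume(bad, c(1, 1, 1), "DOSE"), "negative")
})

test_that("CT preprocessing equalises, rescales and preserves raw HU", {
  ct <- make_ct_volume(c(32, 32, 8))
  pc <- preprocess_ct(ct)
  expect_gte(min(pc$ct_input$voxels), 0)
  expect_lte(max(pc$ct_input$voxels), 1)
  expect_identical(pc$ct_raw_hu$voxels, ct$voxels)

  # tissue masks from raw HU are untouched by preprocessing
  before <- threshold_ct(ct, muscle_window())
  after <- threshold_ct(pc$ct_raw_hu, muscle_window())
  expect_identical(before$voxels, after$voxels)

  # equalisation is rank-based after global rescale: a constant HU shift
  # yields the identical network input
  ct_shift <- volume(ct$voxels + 50, ct$spacing, "CT")
  expect_equal(preprocess_ct(ct_shift)$ct_input$voxels, pc$ct_input$voxels,
               tolerance = 1e-12)

  expect_warning(out <- preprocess_ct(volume(array(0, c(8, 8, 4)), c(1, 1, 1), "CT")),
                 "constant")
  expect_true(all(out$ct_input$voxels == 0))
})

test_that("MRI min-max normalisation spans [0,1] exactly", {
  v <- volume(array(c(0, 50, 100, rep(25, 13)), c(4, 2, 2)), c(1, 1, 1), "MRI")
  n <- preprocess_mri(v)
  expect_equal(range(n$voxels), c(0, 1))
  expect_equal(sort(unique(as.vector(n$voxels))), c(0, 0.25, 0.5, 1))

  v2 <- volume(array(c(-10, 10, rep(0, 6)), c(2, 2, 2)), c(1, 1, 1), "MRI")
  expect_equal(range(preprocess_mri(v2)$voxels), c(0, 1))

  # already-normalised volume is unchanged
  x <- array(runif(64), c(4, 4, 4)); x[1] <- 0; x[2] <- 1
  v3 <- volume(x, c(1, 1, 1), "MRI")
  expect_equal(preprocess_mri(v3)$voxels, x)

  expect_error(preprocess_mri(volume(array(1, c(4, 4, 4)), c(1, 1, 1), "MRI")),
               "degenerate")
})

test_that("resampling is exact on identity grids and keeps masks binary", {
  set.seed(2)
  v <- volume(array(runif(16 * 16 * 8), c(16, 16, 8)), fixture_spacing, "MRI")
  same <- resample_to_grid(v, v, "linear")
  expect_equal(same$voxels, v$voxels, tolerance = 1e-12)

  # constant volume upsampled 2x stays constant
  cv <- volume(array(3, c(8, 8, 4)), c(2, 2, 2), "MRI")
  target <- volume(array(0, c(16, 16, 8)), c(1, 1, 1), "MRI")
  up <- resample_to_grid(cv, target, "linear")
  interior <- up$voxels[2:14, 2:14, 2:7]
  expect_true(all(abs(interior - 3) < 1e-12))

  # nearest keeps a mask binary on a finer grid
  m <- binary_mask(random_mask(c(8, 8, 4)), c(2, 2, 2))
  mr <- resample_to_grid(m, target, "nearest")
  expect_true(all(mr$voxels %in% c(0, 1)))

  far <- volume(array(1, c(4, 4, 4)), c(1, 1, 1), "MRI", origin = c(500, 0, 0))
  expect_error(resample_to_grid(far, target, "linear"), "non-overlapping")
})
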