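test_that("global average pooling is an exact spatial mean", {
  z <- array(2.5, c(4, 4, 4, 3))
  expect_equal(global_average_pool(z), rep(2.5, 3))

  set.seed(3)
  z2 <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  # explicit summation oracle
  expect_equal(global_average_pool(z2),
               c(sum(z2[, , , 1]) / 32, sum(z2[, , , 2]) / 32),
               tolerance = 1e-12)
  # linearity
  expect_equal(global_average_pool(3 * z2), 3 * global_average_pool(z2),
               tolerance = 1e-12)
})

test_that("squeeze-and-excite gates channels through a sigmoid bottleneck", {
  set.seed(4)
  z <- array(rnorm(5 * 5 * 4 * 4), c(5, 5, 4, 4))
  p <- se_params(4, reduction = 2)
  out <- se_block_3d(z, params = p)
  expect_equal(dim(out), dim(z))
  # zero input -> zero output
  expect_true(all(se_block_3d(array(0, dim(z)), params = p) == 0))
  # all gate weights zero -> every channel scaled by sigmoid(0) = 0.5
  p0 <- se_params(4, reduction = 2)
  p0$W1$value[] <- 0; p0$b1$value[] <- 0
  p0$W2$value[] <- 0; p0$b2$value[] <- 0
  expect_equal(se_block_3d(z, params = p0), 0.5 * z, tolerance = 1e-12)
})

test_that("squeeze-and-excite is equivariant under channel permutation", {
  set.seed(5)
  C <- 4
  z <- array(rnorm(4 * 4 * 4 * C), c(4, 4, 4, C))
  p <- se_params(C, reduction = 2)
  perm <- c(3, 1, 4, 2)
  pp <- se_params(C, reduction = 2)
  pp$W1$value <- p$W1$value[perm, , drop = FALSE]
  pp$b1$value <- p$b1$value
  pp$W2$value <- p$W2$value[, perm, drop = FALSE]
  pp$b2$value <- p$b2$value[perm]
  out <- se_block_3d(z, params = p)
  out_p <- se_block_3d(z[, , , perm, drop = FALSE], params = pp)
  expect_equal(out_p, out[, , , perm, drop = FALSE], tolerance = 1e-10)
})

test_that("deformable convolution reduces to identity and shifts as told", {
  set.seed(6)
  z <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  p <- defconv_identity(defconv_params(2, 2))
  expect_equal(deformable_conv_3d(z, params = p), z, tolerance = 1e-12)
  expect_equal(dim(deformable_conv_3d(z, params = defconv_params(2, 3))),
               c(6, 6, 4, 3))

  # constant offset bias compensating a one-voxel translation recovers
  # the untranslated input on the interior
  zs <- z
  zs[2:6, , , ] <- z[1:5, , , ]  # translated by +1 voxel in x
  ps <- defconv_identity(defconv_params(2, 2))
  K <- ps$k^3
  ps$boff$value[seq(1, 3 * K, by = 3)] <- 1  # sample at x + 1
  out <- deformable_conv_3d(zs, params = ps)
  expect_equal(out[2:5, 2:5, 2:3, ], z[2:5, 2:5, 2:3, ], tolerance = 1e-10)
})

test_that("modality attention composes the fusion equations exactly", {
  set.seed(7)
  d <- c(4, 4, 4, 2)
  z_mri <- array(rnorm(prod(d)), d)
  z_ct <- array(rnorm(prod(d)), d)
  p <- list(defconv = defconv_identity(defconv_params(2, 2)))
  got <- modality_attention(z_mri, z_ct, params = p)

  # independent composition: with the deformable alignment forced to
  # identity, fused output = softmax(meanpool(ct + mri)) applied to
  # both streams and summed
  zsum <- z_ct + z_mri
  gp <- apply(zsum, 4, mean)
  w <- exp(gp - max(gp)); w <- w / sum(w)
  expected <- array(0, d)
  for (c in 1:2) expected[, , , c] <- w[c] * (z_ct[, , , c] + z_mri[, , , c])
  expect_equal(got$z_encoder, expected, tolerance = 1e-5)
  expect_equal(got$z_mri_tran, z_mri, tolerance = 1e-10)
  expect_equal(sum(got$weights), 1, tolerance = 1e-6)
  expect_true(all(got$weights > 0))

  # zero inputs: uniform attention, zero fused output
  z0 <- array(0, d)
  got0 <- modality_attention(z0, z0, params = p)
  expect_equal(got0$weights, rep(0.5, 2))
  expect_true(all(got0$z_encoder == 0))

  expect_error(modality_attention(z_mri, array(0, c(4, 4, 2, 2))), "shape")
})

test_that("the network outputs probabilities on the CT grid with two poolings", {
  set.seed(8)
  d <- c(16L, 16L, 8L)
  ct <- volume(array(runif(prod(d)), d), fixture_spacing, "CT", units = "arbitrary")
  mri <- volume(array(runif(prod(d)), d), fixture_spacing, "MRI", units = "arbitrary")
  model <- pudoseg:::new_sunet_model(model_config("snetma", base_channels = 4), seed = 1)
  pm <- sunet_forward(model, ct, mri)
  expect_equal(dim(pm$voxels), d)
  expect_true(all(pm$voxels >= 0 & pm$voxels <= 1))

  # exactly two spatial resolution reductions before the bottleneck
  tr <- new.env()
  ctv <- ct$voxels; dim(ctv) <- c(d, 1L)
  mrv <- mri$voxels; dim(mrv) <- c(d, 1L)
  r <- pudoseg:::with_tape(
    pudoseg:::nd_sunet_forward(ctv, mrv, model$params, model$config, trace = tr))
  expect_equal(tr$pool1[1:3], d %/% 2L)
  expect_equal(tr$pool2[1:3], d %/% 4L)

  # missing MRI is the all-zero fill volume, bitwise
  pm_absent <- sunet_forward(model, ct, NULL)
  zero_mri <- volume(array(0, d), fixture_spacing, "MRI", units = "arbitrary")
  pm_zero <- sunet_forward(model, ct, zero_mri)
  expect_identical(pm_absent$voxels, pm_zero$voxels)

  # grid mismatch rejected
  bad <- volume(array(0.5, c(8, 8, 8)), fixture_spacing, "MRI", units = "arbitrary")
  expect_error(sunet_forward(model, ct, bad), "grid mismatch")

  # non-divisible grids rejected (two pooling levels)
  odd <- volume(array(0.5, c(10, 10, 6)), fixture_spacing, "CT", units = "arbitrary")
  expect_error(sunet_forward(model, odd, NULL), "divisible")

  # single-encoder baseline runs on the same inputs
  model2 <- pudoseg:::new_sunet_model(model_config("snet", base_channels = 4), seed = 1)
  pm2 <- sunet_forward(model2, ct, mri)
  expect_equal(dim(pm2$voxels), d)
  expect_true(all(pm2$voxels >= 0 & pm2$voxels <= 1))
})
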