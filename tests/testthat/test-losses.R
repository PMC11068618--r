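test_that("HU windows threshold raw CT inclusively", {
  hu <- array(c(100, 200, -29, 150, 300, 1200, 299, 1201, -30, 0,
                rep(0, 6)), c(4, 2, 2))
  muscle <- threshold_ct(hu, muscle_window())
  bone <- threshold_ct(hu, bone_window())
  # 100 HU is muscle; 200 HU is neither; bounds are inclusive
  expect_equal(muscle[1], 1)                # 100
  expect_equal(muscle[2] + bone[2], 0)      # 200
  expect_equal(muscle[3], 1)                # -29 inclusive
  expect_equal(muscle[4], 1)                # 150 inclusive
  expect_equal(bone[5], 1)                  # 300 inclusive
  expect_equal(bone[6], 1)                  # 1200 inclusive
  expect_equal(bone[7], 0)                  # 299
  expect_equal(bone[8], 0)                  # 1201
  expect_equal(muscle[9], 0)                # -30

  v <- volume(hu, c(1, 1, 1), "CT")
  expect_equal(as.vector(threshold_ct(v, muscle_window())$voxels),
               as.vector(muscle))
  mriv <- volume(hu, c(1, 1, 1), "MRI")
  expect_error(threshold_ct(mriv, muscle_window()), "HU")
  expect_error(hu_window(150, -29, "muscle"))
})

test_that("Dice loss matches voxel counting on constructed masks", {
  d <- c(6, 6, 6)
  cube <- array(0, d); cube[2:4, 2:4, 2:4] <- 1
  shifted <- array(0, d); shifted[2:4, 2:4, 3:5] <- 1  # overlap 3x3x2
  expect_equal(dsc_loss(cube, cube), 0, tolerance = 1e-4)
  disjoint <- array(0, d); disjoint[5:6, 5:6, 5:6] <- 1
  expect_equal(dsc_loss(cube, disjoint), 1, tolerance = 1e-4)
  # 1 - 2*18/(27+27) = 1/3
  expect_equal(dsc_loss(cube, shifted), 1 / 3, tolerance = 1e-4)
  # jaccard form: 1 - 18/(27+27-18) = 1/2
  expect_equal(dsc_loss(cube, shifted, form = "jaccard"), 1 / 2,
               tolerance = 1e-4)
  # symmetry on binary masks
  expect_equal(dsc_loss(cube, shifted), dsc_loss(shifted, cube))
  expect_error(dsc_loss(cube, array(0, c(4, 4, 4))), "grid mismatch")
})

test_that("inclusion loss is the in-tissue fraction of predicted mass", {
  d <- c(4, 4, 4)
  blob <- array(0, d); blob[1:4, 1, 1] <- 1
  tissue <- array(0, d); tissue[1:2, 1, 1] <- 1  # half the blob
  expect_equal(inclusion_loss(blob, tissue), 0.5, tolerance = 1e-4)
  expect_equal(inclusion_loss(blob, blob), 1, tolerance = 1e-4)
  expect_equal(inclusion_loss(blob, array(0, d)), 0, tolerance = 1e-4)
  # invariant under uniform positive scaling of a soft prediction
  soft <- array(runif(prod(d)), d)
  expect_equal(inclusion_loss(soft, tissue), inclusion_loss(2 * soft, tissue),
               tolerance = 1e-4)
  # growing the tissue mask never decreases the loss
  bigger <- tissue; bigger[3, 1, 1] <- 1
  expect_gte(inclusion_loss(soft, bigger), inclusion_loss(soft, tissue))
})

test_that("combined loss is the weighted sum of its three terms", {
  set.seed(10)
  d <- c(8, 8, 8)
  pred <- array(runif(prod(d)), d)
  gt <- random_mask(d)
  hu <- array(sample(c(-80, 40, 80, 700), prod(d), replace = TRUE), d)
  ct <- volume(hu, c(1, 1, 1), "CT")
  mm <- as.vector(hu >= -29 & hu <= 150)
  bm <- as.vector(hu >= 300 & hu <= 1200)
  w <- loss_weights()  # wm = 0.1, wb = 0.01
  expect_equal(w$wm, 0.1)
  expect_equal(w$wb, 0.01)
  oracle <- dsc_loss(pred, gt) +
    0.1 * inclusion_loss(pred, array(as.numeric(mm), d)) +
    0.01 * inclusion_loss(pred, array(as.numeric(bm), d))
  expect_equal(combined_loss(pred, gt, ct, w), oracle, tolerance = 1e-12)
  # zero weights reduce to the Dice term exactly
  expect_identical(combined_loss(pred, gt, ct, loss_weights(0, 0)),
                   dsc_loss(pred, gt))
  # perfect prediction away from both tissues scores 0
  gt2 <- array(0, d); gt2[hu == -80] <- 1
  expect_equal(combined_loss(gt2, gt2, ct, w), 0, tolerance = 1e-3)
  # bounded by 1 + wm + wb
  expect_lte(combined_loss(pred, gt, ct, w), 1 + w$wm + w$wb)
})

test_that("the training gradient penalises bone inclusion outside the target", {
  set.seed(11)
  d <- c(6, 6, 6)
  gt <- array(0, d); gt[2:3, 2:3, 2:3] <- 1
  bone <- array(0, d); bone[5, 5, 5] <- 1
  muscle <- array(0, d)
  pred0 <- array(0.3, d)
  xp <- pudoseg:::param_new(array(pred0, c(d, 1L)))
  r <- pudoseg:::with_tape({
    pn <- pudoseg:::nd_param(xp)
    pudoseg:::nd_combined_loss(pudoseg:::nd_sigmoid(pn), gt, muscle, bone,
                               weights = loss_weights())
  })
  pudoseg:::tape_backward(r$tape, r$root)
  g <- xp$grad
  dim(g) <- d
  # at the bone voxel (outside gt) the gradient is strictly positive
  expect_gt(g[5, 5, 5], 0)
  # at a target voxel it is negative (push prediction up)
  expect_lt(g[2, 2, 2], 0)
})
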