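train_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bm <- make_benchmark(3, 1, spec = phantom_spec(grid = c(16, 16, 8)),
                           seed = 77)
      cache <<- list(train = prepare_samples(bm$train, label = "noisy"),
                     test = prepare_samples(bm$test, label = "clean"))
    }
    cache
  }
})

test_that("the learning-rate schedule decays exponentially from 0.001", {
  expect_equal(lr_schedule(0), 0.001)
  expect_equal(lr_schedule(5, decay = 1), 0.001)
  expect_equal(lr_schedule(2, 0.001, 0.9), 0.001 * 0.81)
})

test_that("modality dropout drops MRI per sample at the requested rate", {
  fx <- train_fixture()
  batch <- rep(fx$train[1], 4)
  out0 <- modality_dropout(batch, 0)
  expect_false(any(attr(out0, "dropped")))
  expect_false(is.null(out0[[1]]$mri_input))
  out1 <- modality_dropout(batch, 1)
  expect_true(all(attr(out1, "dropped")))
  expect_true(all(vapply(out1, function(s) is.null(s$mri_input), logical(1))))

  set.seed(123)
  n <- 1000
  dropped <- attr(modality_dropout(rep(fx$train[1], n), 0.5), "dropped")
  frac <- mean(dropped)
  # 99 % binomial interval for n = 1000, p = 0.5
  expect_gte(frac, 0.459)
  expect_lte(frac, 0.541)
})

test_that("augmentation transforms all channels together and keeps labels binary", {
  fx <- train_fixture()
  pair <- fx$train[[1]]
  # identity draw
  set.seed(1)
  same <- augment_pair(pair, p_rotate = 0, p_scale = 0, p_flip = 0)
  expect_identical(same$ct_input$voxels, pair$ct_input$voxels)
  expect_identical(same$label$voxels, pair$label$voxels)
  # any draw keeps the label binary and the raw HU value set intact
  set.seed(2)
  aug <- augment_pair(pair, p_rotate = 1, p_scale = 1, p_flip = 1)
  expect_true(all(aug$label$voxels %in% c(0, 1)))
  expect_true(all(aug$ct_raw_hu$voxels %in% unique(as.vector(pair$ct_raw_hu$voxels))))
  expect_equal(dim(aug$mri_input$voxels), dim(pair$mri_input$voxels))
  # double flip along the same axis restores the sample
  set.seed(3)
  f1 <- augment_pair(pair, p_rotate = 0, p_scale = 0, p_flip = 1, flip_axes = 1L)
  f2 <- augment_pair(f1, p_rotate = 0, p_scale = 0, p_flip = 1, flip_axes = 1L)
  expect_identical(f2$ct_input$voxels, pair$ct_input$voxels)
  expect_identical(f2$label$voxels, pair$label$voxels)
  # rotations above the cap are rejected
  expect_error(augment_pair(pair, max_rotation_deg = 12), "max_rotation_deg")
})

test_that("training runs, is seeded-reproducible, and regimes coincide when p = 0", {
  fx <- train_fixture()
  fit <- sunet(fx$train, variant = "snetma", base_channels = 4, epochs = 1,
               modo_probability = 0.5, seed = 1)
  expect_s3_class(fit, "sunet")
  expect_true(is.finite(fit$history$loss[1]))
  expect_equal(nrow(fit$history), 1)

  # same seed and config -> identical first-epoch loss
  fit2 <- sunet(fx$train, variant = "snetma", base_channels = 4, epochs = 1,
                modo_probability = 0.5, seed = 1)
  expect_equal(fit$history$loss[1], fit2$history$loss[1], tolerance = 1e-6)

  # p = 0 reproduces the no-dropout regime exactly
  fit_p0 <- sunet(fx$train, variant = "snetma", base_channels = 4, epochs = 1,
                  modo_probability = 0, seed = 5)
  pre <- ablation_preset("mrict")
  fit_mrict <- sunet(fx$train, variant = pre$variant, weights = pre$weights,
                     modo_probability = pre$modo_probability,
                     base_channels = 4, epochs = 1, seed = 5)
  expect_equal(fit_p0$history$loss[1], fit_mrict$history$loss[1],
               tolerance = 1e-9)

  # fit methods
  expect_output(print(fit), "modality dropout")
  sm <- summary(fit)
  expect_gt(sm$n_parameters, 1000)
  expect_type(coef(fit), "list")
  pdf(NULL); plot(fit); dev.off()
})

test_that("a small network overfits one phantom (the benchmark is learnable)", {
  fx <- train_fixture()
  pair <- fx$train[[1]]
  fit <- sunet(list(pair), variant = "snetma", base_channels = 6,
               epochs = 150, batch_size = 1, initial_lr = 0.01, lr_decay = 1,
               modo_probability = 0, weights = loss_weights(0, 0), seed = 2)
  # loss after optimisation is far below the starting loss
  expect_lt(fit$history$loss[150], fit$history$loss[1] - 0.3)
  pm <- predict(fit, pair, type = "mask")
  expect_gt(dsc(pm$voxels, as_array3d(pair$label)), 95)
})

test_that("checkpoints round-trip weights and predictions", {
  fx <- train_fixture()
  fit <- sunet(fx$train, variant = "snetma", base_channels = 4, epochs = 1,
               seed = 3)
  f <- tempfile(fileext = ".ckpt")
  sunet_save(fit, f)
  fit2 <- sunet_load(f)
  p1 <- predict(fit, fx$test[[1]])
  p2 <- predict(fit2, fx$test[[1]])
  expect_identical(p1$voxels, p2$voxels)
})

test_that("a validation split selects and restores the best-scoring weights", {
  fx <- train_fixture()
  fit <- sunet(fx$train, variant = "snetma", base_channels = 4, epochs = 3,
               val_fraction = 0.34, seed = 9)
  expect_false(is.na(fit$best_epoch))
  expect_true(any(is.finite(fit$history$val_dsc)))
  # the stored best epoch attains the maximum recorded validation DSC
  expect_equal(fit$history$val_dsc[fit$best_epoch + 1],
               max(fit$history$val_dsc, na.rm = TRUE))
})

test_that("fold assignment and patch sampling are seeded and shape-correct", {
  f1 <- crossval_folds(10, 3, seed = 4)
  f2 <- crossval_folds(10, 3, seed = 4)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:3)
  expect_lte(max(table(f1)) - min(table(f1)), 1)

  fx <- train_fixture()
  set.seed(6)
  patch <- sample_patch(fx$train[[1]], c(8, 8, 4))
  expect_equal(dim(patch$ct_input$voxels), c(8L, 8L, 4L))
  expect_equal(dim(patch$label$voxels), c(8L, 8L, 4L))
  expect_true(all(patch$label$voxels %in% c(0, 1)))
  expect_error(sample_patch(fx$train[[1]], c(6, 6, 4)), "multiples of 4")
})
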