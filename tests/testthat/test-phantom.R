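test_that("phantom generation is deterministic and anatomically coherent", {
  spec <- phantom_spec(grid = c(24, 24, 16), seed = 42,
                       misregistration_mm = c(1.5, -1, 0.5))
  s1 <- generate_phantom(spec)
  s2 <- generate_phantom(spec)
  expect_identical(s1$ct$voxels, s2$ct$voxels)
  expect_identical(s1$mri_native$voxels, s2$mri_native$voxels)
  expect_identical(s1$label_noisy$voxels, s2$label_noisy$voxels)

  # clean label is a subset of the noisy label
  expect_true(all(s1$label$voxels <= s1$label_noisy$voxels))

  # two connected curvilinear vessel components (6-connectivity)
  lab <- s1$regions$vessel
  comp <- local({
    visited <- array(FALSE, dim(lab))
    ncomp <- 0
    idx <- which(lab & !visited)
    while (length(idx) > 0) {
      ncomp <- ncomp + 1
      queue <- idx[1]
      visited[queue] <- TRUE
      d <- dim(lab)
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        k <- (v - 1) %/% (d[1] * d[2]); r <- (v - 1) %% (d[1] * d[2])
        j <- r %/% d[1]; i <- r %% d[1]
        for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
          ni <- i + off[1]; nj <- j + off[2]; nk <- k + off[3]
          if (ni < 0 || ni >= d[1] || nj < 0 || nj >= d[2] || nk < 0 || nk >= d[3]) next
          nv <- 1 + ni + nj * d[1] + nk * d[1] * d[2]
          if (lab[nv] && !visited[nv]) { visited[nv] <- TRUE; queue <- c(queue, nv) }
        }
      }
      idx <- which(lab & !visited)
    }
    ncomp
  })
  expect_equal(comp, 2)
})

test_that("noiseless CT thresholding recovers the generator's region maps", {
  spec <- phantom_spec(grid = c(24, 24, 16), seed = 5,
                       noise_sigma = c(ct = 0, mri = 0))
  s <- generate_phantom(spec)
  bone_rec <- as_logical <- threshold_ct(s$ct, bone_window())$voxels > 0.5
  expect_identical(bone_rec, s$regions$bone)
  # the muscle window recovers muscle plus vessel: the vessel's 80 HU
  # lies inside the muscle window by design
  muscle_rec <- threshold_ct(s$ct, muscle_window())$voxels > 0.5
  expect_identical(muscle_rec, s$regions$muscle | s$regions$vessel)
})

test_that("noisy labels reach into bone when the dilation spans the gap", {
  spec <- phantom_spec(grid = c(24, 24, 16), seed = 9,
                       label_noise_dilation_mm = 4, label_noise_keep = 1)
  s <- generate_phantom(spec)
  extra <- s$label_noisy$voxels > 0.5 & s$label$voxels < 0.5
  expect_gt(sum(extra & s$regions$bone), 0)
  expect_gt(sum(extra & s$regions$muscle), 0)
  # no noise outside tissue (never into background fat)
  expect_equal(sum(extra & !(s$regions$muscle | s$regions$bone | s$regions$vessel)), 0)

  # zero dilation reproduces the clean label
  s0 <- generate_phantom(phantom_spec(grid = c(24, 24, 16), seed = 9,
                                      label_noise_dilation_mm = 0))
  expect_identical(s0$label_noisy$voxels, s0$label$voxels)
})

test_that("MRI carries at least 3x the vessel contrast-to-noise of CT", {
  for (seed in c(1, 2, 3)) {
    s <- generate_phantom(phantom_spec(grid = c(24, 24, 16), seed = seed))
    cnr <- function(vox, reg) {
      abs(mean(vox[reg$vessel]) - mean(vox[reg$muscle])) / stats::sd(vox[reg$muscle])
    }
    cnr_ct <- cnr(s$ct$voxels, s$regions)
    cnr_mri <- cnr(s$mri_native$voxels, s$regions_mri)
    expect_gte(cnr_mri / cnr_ct, 3)
  }
})

test_that("misregistration translates content and approximately inverts", {
  # a smooth field (interpolation error vanishes on smooth content)
  d <- c(16, 16, 8)
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  v <- volume(array(sin(co$x / 4) * cos(co$y / 5) + co$z / 10, d),
              fixture_spacing, "MRI")
  expect_identical(apply_misregistration(v, c(0, 0, 0))$voxels, v$voxels)
  cst <- volume(array(2, c(8, 8, 8)), c(1, 1, 1), "MRI")
  expect_equal(apply_misregistration(cst, c(1.3, -0.7, 0.4))$voxels, cst$voxels)
  off <- c(1.8, -1.1, 0.9)
  fwd <- apply_misregistration(v, off)
  back <- apply_misregistration(fwd, -off)
  interior <- back$voxels[5:12, 5:12, 3:6]
  expect_lt(max(abs(interior - v$voxels[5:12, 5:12, 3:6])), 0.05)
})

test_that("caudal label clipping follows the PTV margin in slices", {
  d <- c(8, 8, 20)
  label <- array(0, d); label[4:5, 4:5, ] <- 1
  ptv <- array(0, d); ptv[3:6, 3:6, 9:16] <- 1
  sp <- c(1, 1, 2.5)
  # margin 10 mm at 2.5 mm slices -> exactly 4 slices beyond the most
  # caudal PTV slice (slice 9) survive: slices 5..8
  out <- clip_label_extent(label, ptv, 10, spacing = sp)
  kept <- which(apply(out > 0, 3, any))
  expect_equal(min(kept), 5)
  expect_equal(sum(out[, , 1:4]), 0)
  expect_equal(sum(out[, , 5:20]), sum(label[, , 5:20]))
  # margin 0 clips at the last PTV slice
  out0 <- clip_label_extent(label, ptv, 0, spacing = sp)
  expect_equal(min(which(apply(out0 > 0, 3, any))), 9)
  # a label inside the PTV range is untouched
  lab2 <- array(0, d); lab2[4, 4, 10:14] <- 1
  expect_identical(clip_label_extent(lab2, ptv, 10, spacing = sp), lab2)
  expect_error(clip_label_extent(label, array(0, d), 10, spacing = sp), "empty PTV")
})

test_that("benchmark generation writes reproducible NIfTI datasets", {
  spec <- phantom_spec(grid = c(16, 16, 8))
  dir1 <- file.path(tempdir(), "bench1")
  dir2 <- file.path(tempdir(), "bench2")
  b1 <- make_benchmark(2, 1, spec = spec, seed = 3, out_dir = dir1)
  b2 <- make_benchmark(2, 1, spec = spec, seed = 3, out_dir = dir2)
  expect_equal(length(b1$train), 2)
  expect_equal(length(b1$test), 1)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_equal(length(list.dirs(dir1, recursive = FALSE)), 3)
  # same seed -> identical content checksums
  md5_1 <- vapply(b1$manifest$files, function(f) f$md5, character(1))
  md5_2 <- vapply(b2$manifest$files, function(f) f$md5, character(1))
  expect_identical(md5_1, md5_2)
  # every generated CT contains voxels in both tissue windows
  for (s in c(b1$train, b1$test)) {
    expect_gt(sum(threshold_ct(s$ct, muscle_window())$voxels), 0)
    expect_gt(sum(threshold_ct(s$ct, bone_window())$voxels), 0)
  }
  # train/test draws differ
  expect_false(identical(b1$train[[1]]$ct$voxels, b1$test[[1]]$ct$voxels))
  # disk round-trip reproduces the in-memory volumes
  rb <- read_benchmark(dir1)
  expect_equal(rb$train[[1]]$ct$voxels, b1$train[[1]]$ct$voxels,
               tolerance = 1e-6)
  expect_equal(rb$test[[1]]$label$voxels, b1$test[[1]]$label$voxels)
})
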