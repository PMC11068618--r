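# Training harness: modality dropout, geometric augmentation, Adam with
# exponential learning-rate decay, and the classed model-fit object.

#' Exponentially decayed learning rate
#'
#' `initial_lr * decay^epoch` (epoch counted from 0).
#'
#' @param epoch epoch index >= 0.
#' @param initial_lr initial learning rate (default 0.001).
#' @param decay per-epoch decay factor (1 = constant).
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, initial_lr = 0.001, decay = 0.97) {
  stopifnot(epoch >= 0)
  initial_lr * decay^epoch
}

#' Modality dropout over a batch
#'
#' Independently per sample, with probability `p` the MRI input is
#' dropped (replaced downstream by the all-zero fill volume); CT is
#' never dropped.  The per-sample decisions are attached as attribute
#' `"dropped"`.
#'
#' @param batch list of `preprocessed_pair`s.
#' @param p dropout probability in \[0,1\].
#' @return the batch with dropped MRIs set to `NULL`.
#' @export
modality_dropout <- function(batch, p) {
  stopifnot(p >= 0, p <= 1)
  dropped <- logical(length(batch))
  for (i in seq_along(batch)) {
    if (!is.null(batch[[i]]$mri_input) && p > 0 && stats::runif(1) < p) {
      batch[[i]]$mri_input <- NULL
      dropped[i] <- TRUE
    }
  }
  attr(batch, "dropped") <- dropped
  batch
}

# rotate (about the slice axis) + isotropic scale about the volume
# centre; linear interpolation with edge clamping for intensities,
# nearest for labels/raw HU so value sets are preserved
affine_resample_3d <- function(x, spacing, angle_deg, scale, nearest = FALSE) {
  d <- dim(x)
  bc <- base_coords(d)
  ctr <- (d + 1) / 2
  cx <- (bc$x - ctr[1]) * spacing[1]
  cy <- (bc$y - ctr[2]) * spacing[2]
  cz <- (bc$z - ctr[3]) * spacing[3]
  th <- -angle_deg * pi / 180  # inverse map
  sx <- cos(th) * cx - sin(th) * cy
  sy <- sin(th) * cx + cos(th) * cy
  sx <- sx / scale; sy <- sy / scale; sz <- cz / scale
  ix <- pmin(pmax(sx / spacing[1] + ctr[1], 1), d[1])
  iy <- pmin(pmax(sy / spacing[2] + ctr[2], 1), d[2])
  iz <- pmin(pmax(sz / spacing[3] + ctr[3], 1), d[3])
  if (nearest) {
    array(nearest_gather(as.vector(x), d, ix, iy, iz), d)
  } else {
    xm <- x; dim(xm) <- c(prod(d), 1L)
    array(trilinear_gather(xm, d, ix, iy, iz)[, 1], d)
  }
}

flip_array <- function(x, axis) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  x[idx[[1]], idx[[2]], idx[[3]]]
}

#' Random geometric augmentation of a training sample
#'
#' One random in-plane rotation (|angle| < `max_rotation_deg`), one
#' isotropic scale and random flips, applied identically to CT, MRI,
#' raw HU and label.  Intensities are interpolated linearly; the label
#' and the raw HU volume use nearest-neighbour resampling, so the label
#' stays binary and HU window membership is preserved.  Applied in the
#' order rotate, scale, flip, each with its own probability.
#'
#' @param pair a `preprocessed_pair` (see [preprocess_pair()]).
#' @param max_rotation_deg maximum rotation magnitude (must be < 10).
#' @param scale_range isotropic scale interval.
#' @param flip_axes axes eligible for flipping (default 1, left-right).
#' @param p_rotate,p_scale,p_flip per-transform probabilities.
#' @return augmented `preprocessed_pair`.
#' @export
augment_pair <- function(pair, max_rotation_deg = 8, scale_range = c(0.95, 1.05),
                         flip_axes = 1L, p_rotate = 0.5, p_scale = 0.5,
                         p_flip = 0.5) {
  stopifnot(max_rotation_deg < 10)
  angle <- if (stats::runif(1) < p_rotate)
    stats::runif(1, -max_rotation_deg, max_rotation_deg) else 0
  scale <- if (stats::runif(1) < p_scale)
    stats::runif(1, scale_range[1], scale_range[2]) else 1
  flips <- flip_axes[stats::runif(length(flip_axes)) < p_flip]
  sp <- pair$ct_input$spacing
  tx <- function(v, nearest) {
    if (is.null(v)) return(NULL)
    out <- v
    if (angle != 0 || scale != 1) {
      out$voxels <- affine_resample_3d(out$voxels, sp, angle, scale, nearest)
    }
    for (ax in flips) out$voxels <- flip_array(out$voxels, ax)
    out
  }
  pair$ct_input <- tx(pair$ct_input, nearest = FALSE)
  pair$mri_input <- tx(pair$mri_input, nearest = FALSE)
  pair$ct_raw_hu <- tx(pair$ct_raw_hu, nearest = TRUE)
  pair$label <- tx(pair$label, nearest = TRUE)
  pair
}

#' Convert phantom samples to training pairs
#'
#' Runs the standard preprocessing (CLAHE + min-max, MRI resampled to
#' the CT grid) on each phantom and attaches the chosen label.
#'
#' @param samples list of `phantom_sample`s (or a `make_benchmark()`
#'   train/test element).
#' @param label `"clean"` or `"noisy"` -- which label to train against.
#' @param use_mri include the MRI input (FALSE emulates a CT-only
#'   dataset).
#' @return list of `preprocessed_pair`s.
#' @export
prepare_samples <- function(samples, label = c("clean", "noisy"),
                            use_mri = TRUE) {
  label <- match.arg(label)
  lapply(samples, function(s) {
    stopifnot(inherits(s, "phantom_sample"))
    lab <- if (label == "clean") s$label else s$label_noisy
    preprocess_pair(s$ct, mri = if (use_mri) s$mri else NULL, label = lab)
  })
}

sample_tensors <- function(pair, muscle, bone) {
  ct <- pair$ct_input$voxels
  d <- dim(ct)
  dim(ct) <- c(d, 1L)
  mri <- NULL
  if (!is.null(pair$mri_input)) {
    mri <- pair$mri_input$voxels
    dim(mri) <- c(d, 1L)
  }
  raw <- pair$ct_raw_hu$voxels
  list(ct = ct, mri = mri,
       gt = as_array3d(pair$label),
       muscle = threshold_ct(raw, muscle),
       bone = threshold_ct(raw, bone))
}

adam_step <- function(plist, lr, t, scale = 1, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (p in plist) {
    g <- p$grad * scale
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- p$grad * 0
  }
  invisible(NULL)
}

#' Fit the segmentation network
#'
#' Trains a squeeze-and-excite U-Net (with or without modality
#' attention) on preprocessed CT/MRI pairs with the combined objective
#' (soft Dice + weighted muscle/bone inclusion losses on HU-thresholded
#' raw CT), Adam with exponential learning-rate decay, optional
#' geometric augmentation and modality dropout.  Deterministic given
#' `seed` and configuration.
#'
#' @param samples list of `preprocessed_pair`s with labels (see
#'   [prepare_samples()]).
#' @param variant,base_channels,se_reduction,deformable_kernel see
#'   [model_config()].
#' @param epochs training epochs.
#' @param batch_size samples per optimiser step (default 4).
#' @param initial_lr,lr_decay Adam learning-rate schedule, see
#'   [lr_schedule()].
#' @param modo_probability modality-dropout probability (0 reproduces
#'   the no-dropout regime; 1 trains CT-only).
#' @param weights [loss_weights()]; `loss_weights(0, 0)` trains with
#'   the Dice term alone.
#' @param muscle,bone HU windows for the inclusion losses.
#' @param loss_form `"dice"` or `"jaccard"` overlap denominator.
#' @param epsilon loss smoothing constant.
#' @param augment logical; apply [augment_pair()] per sample.
#' @param augment_cfg list of [augment_pair()] arguments.
#' @param val_fraction fraction of samples held out to select the
#'   best-validation-DSC weights (0 keeps the final weights).
#' @param patience early-stopping patience on validation DSC (epochs);
#'   `Inf` disables early stopping.
#' @param threshold binarisation threshold for validation DSC.
#' @param seed RNG seed covering weight init, shuffling, dropout and
#'   augmentation.
#' @param verbose print per-epoch progress.
#' @return object of class `sunet` with elements `model`
#'   (`sunet_model`), `history` (per-epoch data frame), `best_epoch`
#'   and the training configuration.
#' @export
sunet <- function(samples, variant = c("snetma", "snet"), base_channels = 16,
                  se_reduction = 4, deformable_kernel = 3L, epochs = 20,
                  batch_size = 4, initial_lr = 0.001, lr_decay = 0.97,
                  modo_probability = 0.5, weights = loss_weights(),
                  muscle = muscle_window(), bone = bone_window(),
                  loss_form = c("dice", "jaccard"), epsilon = 1e-5,
                  augment = FALSE, augment_cfg = list(),
                  val_fraction = 0, patience = Inf, threshold = 0.5,
                  seed = 1L, verbose = FALSE) {
  variant <- match.arg(variant)
  loss_form <- match.arg(loss_form)
  stopifnot(length(samples) > 0)
  for (s in samples) {
    if (is.null(s$label)) stop("every training sample needs a label")
  }
  set.seed(seed)
  cfg <- model_config(variant, base_channels, se_reduction, deformable_kernel)
  model <- structure(list(config = cfg, params = sunet_params(cfg)),
                     class = "sunet_model")
  plist <- collect_params(model$params)

  n <- length(samples)
  n_val <- floor(val_fraction * n)
  perm <- sample(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(perm, val_idx)
  if (length(train_idx) == 0L) stop("no training samples left after validation split")

  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_dsc = numeric(0), lr = numeric(0))
  best <- list(dsc = -Inf, epoch = NA_integer_, snap = NULL)
  step_t <- 0L
  stall <- 0L

  val_dsc <- function() {
    if (length(val_idx) == 0L) return(NA_real_)
    vs <- vapply(val_idx, function(i) {
      s <- samples[[i]]
      ts <- sample_tensors(s, muscle, bone)
      r <- with_tape(nd_sunet_forward(ts$ct, ts$mri, model$params, cfg))
      pr <- r$root$val; dim(pr) <- dim(ts$gt)
      dsc(pr >= threshold, ts$gt)
    }, numeric(1))
    mean(vs)
  }

  for (epoch in seq_len(epochs) - 1L) {
    lr <- lr_schedule(epoch, initial_lr, lr_decay)
    ord <- sample(train_idx)
    ep_loss <- 0
    n_seen <- 0L
    for (b0 in seq(1, length(ord), by = batch_size)) {
      bidx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      batch <- samples[bidx]
      if (augment) {
        batch <- lapply(batch, function(p) do.call(augment_pair, c(list(p), augment_cfg)))
      }
      batch <- modality_dropout(batch, modo_probability)
      for (p in batch) {
        ts <- sample_tensors(p, muscle, bone)
        r <- with_tape({
          pred <- nd_sunet_forward(ts$ct, ts$mri, model$params, cfg)
          nd_combined_loss(pred, ts$gt, ts$muscle, ts$bone,
                           weights = weights, eps = epsilon, form = loss_form)
        })
        if (!is.finite(r$root$val)) {
          stop(sprintf("non-finite loss at epoch %d (lr %.3g): aborting", epoch, lr))
        }
        tape_backward(r$tape, r$root)
        ep_loss <- ep_loss + r$root$val
        n_seen <- n_seen + 1L
      }
      step_t <- step_t + 1L
      adam_step(plist, lr, step_t, scale = 1 / length(batch))
    }
    vd <- val_dsc()
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss / n_seen,
                                   val_dsc = vd, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val DSC %s  lr %.2e", epoch,
                      ep_loss / n_seen,
                      ifelse(is.na(vd), "--", sprintf("%.1f", vd)), lr))
    }
    if (!is.na(vd) && vd > best$dsc) {
      best <- list(dsc = vd, epoch = epoch, snap = params_snapshot(model$params))
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  if (!is.null(best$snap)) params_restore(model$params, best$snap)

  structure(list(model = model, history = hist,
                 best_epoch = best$epoch,
                 config = list(variant = variant, base_channels = base_channels,
                               epochs = epochs, batch_size = batch_size,
                               initial_lr = initial_lr, lr_decay = lr_decay,
                               modo_probability = modo_probability,
                               weights = weights, loss_form = loss_form,
                               epsilon = epsilon, augment = augment,
                               val_fraction = val_fraction,
                               threshold = threshold, seed = seed)),
            class = "sunet")
}

#' @export
print.sunet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Squeeze-and-excite U-Net fit (%s)\n", cfg$variant))
  cat(sprintf("  base channels %d, 2 pooling levels, modality dropout p = %g\n",
              x$model$config$base_channels, cfg$modo_probability))
  cat(sprintf("  loss: soft %s + %g * muscle inclusion + %g * bone inclusion\n",
              cfg$loss_form, cfg$weights$wm, cfg$weights$wb))
  cat(sprintf("  trained %d epoch(s); final loss %.4f\n",
              nrow(x$history), utils::tail(x$history$loss, 1)))
  if (!is.na(x$best_epoch %||% NA)) {
    cat(sprintf("  best validation DSC %.1f%% at epoch %d\n",
                max(x$history$val_dsc, na.rm = TRUE), x$best_epoch))
  }
  invisible(x)
}

#' @export
summary.sunet <- function(object, ...) {
  np <- sum(vapply(collect_params(object$model$params),
                   function(p) length(p$value), numeric(1)))
  out <- list(variant = object$config$variant,
              n_parameters = np,
              epochs_run = nrow(object$history),
              final_loss = utils::tail(object$history$loss, 1),
              best_epoch = object$best_epoch,
              history = object$history)
  class(out) <- "summary.sunet"
  out
}

#' @export
print.summary.sunet <- function(x, ...) {
  cat(sprintf("sunet fit: variant %s, %d parameters, %d epochs\n",
              x$variant, x$n_parameters, x$epochs_run))
  cat(sprintf("final training loss %.4f\n", x$final_loss))
  print(utils::tail(x$history, 5))
  invisible(x)
}

#' @export
coef.sunet <- function(object, ...) {
  lapply(collect_params(object$model$params), function(p) p$value)
}

#' @export
plot.sunet <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss",
                 main = "training history", ...)
  if (any(!is.na(h$val_dsc))) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(h$epoch, h$val_dsc, type = "l", col = "red3",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "red3")
    graphics::mtext("validation DSC (%)", side = 4, line = 2, col = "red3")
  }
  invisible(x)
}

#' Predict a segmentation from a fitted network
#'
#' @param object a fitted [sunet()] object.
#' @param ct CT input: either a `preprocessed_pair`, a preprocessed CT
#'   volume, or a raw HU CT volume (preprocessed automatically).
#' @param mri optional MRI volume (ignored if `ct` is a pair).
#' @param type `"prob"` for the probability map, `"mask"` for the
#'   thresholded binary mask.
#' @param threshold binarisation threshold (default from the fit).
#' @param ... unused.
#' @return a probability-map or mask [volume()] on the CT grid.
#' @export
predict.sunet <- function(object, ct, mri = NULL, type = c("prob", "mask"),
                          threshold = NULL, ...) {
  type <- match.arg(type)
  if (is.null(threshold)) threshold <- object$config$threshold %||% 0.5
  if (inherits(ct, "preprocessed_pair")) {
    pair <- ct
  } else if (is_volume(ct) && ct$units == "HU") {
    pair <- preprocess_pair(ct, mri = mri)
  } else {
    stopifnot(is_volume(ct))
    pair <- list(ct_input = ct, mri_input = mri)
  }
  pm <- sunet_forward(object$model, pair$ct_input, pair$mri_input)
  if (type == "mask") {
    return(binary_mask(pm$voxels >= threshold, pm$spacing, origin = pm$origin))
  }
  pm
}

#' Seeded k-fold split
#'
#' Assigns `n` samples to `k` folds of near-equal size in a random,
#' seed-reproducible order; the building block for cross-validated
#' training runs.
#'
#' @param n number of samples.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return integer vector of length `n` with fold labels in `1:k`.
#' @export
crossval_folds <- function(n, k = 5, seed = 1L) {
  stopifnot(k >= 2, k <= n)
  run_with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Extract a random training patch
#'
#' Cuts an aligned sub-volume (all channels and the label together)
#' out of a preprocessed pair.  Whole phantom volumes train directly;
#' clinical-resolution grids would be fed through this sampler.
#'
#' @param pair a `preprocessed_pair`.
#' @param size integer 3-vector patch size (each component a multiple
#'   of 4, not larger than the grid).
#' @return a `preprocessed_pair` on the patch grid.
#' @export
sample_patch <- function(pair, size) {
  size <- as.integer(size)
  d <- dim(pair$ct_input$voxels)
  if (any(size %% 4L != 0L) || any(size > d)) {
    stop("patch size must be multiples of 4 and fit inside the grid")
  }
  lo <- vapply(1:3, function(a) sample.int(d[a] - size[a] + 1L, 1L), integer(1))
  hi <- lo + size - 1L
  crop <- function(v) {
    if (is.null(v)) return(NULL)
    v$voxels <- v$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    v$origin <- v$origin + (lo - 1) * v$spacing
    v
  }
  pair$ct_input <- crop(pair$ct_input)
  pair$mri_input <- crop(pair$mri_input)
  pair$ct_raw_hu <- crop(pair$ct_raw_hu)
  pair$label <- crop(pair$label)
  pair
}
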