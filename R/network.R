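#' Model configuration
#'
#' The backbone is a 3D U-Net deliberately limited to exactly two
#' pooling levels so thin tubular targets survive downsampling, with a
#' squeeze-and-excite block closing every convolution block.  Variant
#' `"snetma"` uses two separate encoders (CT and MRI) fused by the
#' modality-attention block on every skip connection and at the
#' bottleneck; variant `"snet"` is the single-encoder baseline taking
#' stacked CT+MRI as a 2-channel input, with plain skip connections.
#'
#' @param variant `"snetma"` (dual encoder + modality attention) or
#'   `"snet"` (single encoder, 2-channel input).
#' @param base_channels channels of the first level (default 16), doubled per level.
#' @param se_reduction squeeze-and-excite bottleneck ratio.
#' @param deformable_kernel odd kernel size of the deformable
#'   convolution inside modality attention.
#' @return list of class `sunet_config`.
#' @export
model_config <- function(variant = c("snetma", "snet"), base_channels = 16,
                         se_reduction = 4, deformable_kernel = 3L) {
  variant <- match.arg(variant)
  stopifnot(base_channels >= 2, deformable_kernel %% 2 == 1)
  structure(list(variant = variant, base_channels = as.integer(base_channels),
                 pooling_levels = 2L, se_reduction = se_reduction,
                 deformable_kernel = as.integer(deformable_kernel)),
            class = "sunet_config")
}

in_params <- function(C) {
  list(gamma = param_new(rep(1, C)), beta = param_new(numeric(C)))
}

conv_block_params <- function(cin, cout, reduction) {
  list(c1 = conv_params(cin, cout), n1 = in_params(cout),
       c2 = conv_params(cout, cout), n2 = in_params(cout),
       se = se_params(cout, reduction))
}

nd_conv_block <- function(x, p) {
  h <- nd_relu(nd_instancenorm(nd_conv3d(x, p$c1$W, p$c1$b), p$n1$gamma, p$n1$beta))
  h <- nd_relu(nd_instancenorm(nd_conv3d(h, p$c2$W, p$c2$b), p$n2$gamma, p$n2$beta))
  nd_se(h, p$se)
}

sunet_params <- function(cfg) {
  C <- cfg$base_channels; r <- cfg$se_reduction; k <- cfg$deformable_kernel
  if (cfg$variant == "snetma") {
    list(
      enc_ct = list(b0 = conv_block_params(1L, C, r),
                    b1 = conv_block_params(C, 2L * C, r),
                    bb = conv_block_params(2L * C, 4L * C, r)),
      enc_mri = list(b0 = conv_block_params(1L, C, r),
                     b1 = conv_block_params(C, 2L * C, r),
                     bb = conv_block_params(2L * C, 4L * C, r)),
      ma0 = ma_params(C, k), ma1 = ma_params(2L * C, k),
      mab = ma_params(4L * C, k),
      dec1 = conv_block_params(6L * C, 2L * C, r),
      dec0 = conv_block_params(3L * C, C, r),
      out = conv_params(C, 1L, k = 1L)
    )
  } else {
    list(
      enc = list(b0 = conv_block_params(2L, C, r),
                 b1 = conv_block_params(C, 2L * C, r),
                 bb = conv_block_params(2L * C, 4L * C, r)),
      dec1 = conv_block_params(6L * C, 2L * C, r),
      dec0 = conv_block_params(3L * C, C, r),
      out = conv_params(C, 1L, k = 1L)
    )
  }
}

collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (is.environment(v)) { out[[length(out) + 1L]] <<- v; return(invisible()) }
    if (is.list(v)) for (e in v) walk(e)
    invisible()
  }
  walk(x)
  out
}

params_snapshot <- function(pars) lapply(collect_params(pars), function(p) p$value)

params_restore <- function(pars, snap) {
  ps <- collect_params(pars)
  stopifnot(length(ps) == length(snap))
  for (i in seq_along(ps)) ps[[i]]$value <- snap[[i]]
  invisible(pars)
}

check_input_dims <- function(d) {
  if (any(d[1:3] %% 4L != 0L)) {
    stop("spatial dimensions must be divisible by 4 (two pooling levels)")
  }
  invisible(TRUE)
}

# Tape forward pass.  ct, mri: (X,Y,Z,1) arrays (mri may be NULL -> zero
# fill, the same representation used by modality dropout).  Returns the
# sigmoid prediction node; intermediate shapes are recorded on `trace`
# when a collector environment is supplied.
nd_sunet_forward <- function(ct, mri, pars, cfg, trace = NULL) {
  d <- dim(ct)
  check_input_dims(d)
  if (is.null(mri)) mri <- array(0, d)
  note <- function(name, nd) {
    if (!is.null(trace)) trace[[name]] <- dim(nd$val)
    nd
  }
  if (cfg$variant == "snetma") {
    xc <- nd_const(ct); xm <- nd_const(mri)
    e0c <- nd_conv_block(xc, pars$enc_ct$b0)
    e1c <- nd_conv_block(note("pool1", nd_maxpool2(e0c)), pars$enc_ct$b1)
    ebc <- nd_conv_block(note("pool2", nd_maxpool2(e1c)), pars$enc_ct$bb)
    e0m <- nd_conv_block(xm, pars$enc_mri$b0)
    e1m <- nd_conv_block(nd_maxpool2(e0m), pars$enc_mri$b1)
    ebm <- nd_conv_block(nd_maxpool2(e1m), pars$enc_mri$bb)
    f0 <- nd_modality_attention(e0m, e0c, pars$ma0)$out
    f1 <- nd_modality_attention(e1m, e1c, pars$ma1)$out
    fb <- nd_modality_attention(ebm, ebc, pars$mab)$out
  } else {
    x2 <- array(0, c(d[1:3], 2L))
    x2[, , , 1L] <- ct
    x2[, , , 2L] <- mri
    xn <- nd_const(x2)
    f0 <- nd_conv_block(xn, pars$enc$b0)
    f1 <- nd_conv_block(note("pool1", nd_maxpool2(f0)), pars$enc$b1)
    fb <- nd_conv_block(note("pool2", nd_maxpool2(f1)), pars$enc$bb)
  }
  u1 <- nd_upsample2(fb, dim(f1$val)[1:3])
  d1 <- nd_conv_block(nd_concat(u1, f1), pars$dec1)
  u0 <- nd_upsample2(d1, dim(f0$val)[1:3])
  d0 <- nd_conv_block(nd_concat(u0, f0), pars$dec0)
  logits <- nd_conv3d(d0, pars$out$W, pars$out$b, k = 1L)
  nd_sigmoid(logits)
}

new_sunet_model <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(config = cfg, params = sunet_params(cfg)),
            class = "sunet_model")
}

#' Forward pass of the segmentation network
#'
#' Runs the network on preprocessed inputs and returns a probability
#' map on the CT grid (sigmoid output in \[0,1\]).  A missing MRI is
#' represented as an all-zero volume on the MRI encoder -- exactly the
#' representation used by modality dropout during training.
#'
#' @param model a `sunet_model` (e.g. `fit$model` from [sunet()]).
#' @param ct_input preprocessed CT [volume()] (values in \[0,1\]).
#' @param mri_input preprocessed MRI volume on the CT grid, or `NULL`.
#' @return probability-map `volume` (modality `"MASK"`, units
#'   `"arbitrary"`).
#' @export
sunet_forward <- function(model, ct_input, mri_input = NULL) {
  stopifnot(inherits(model, "sunet_model"), is_volume(ct_input))
  ctv <- ct_input$voxels
  mrv <- NULL
  if (!is.null(mri_input)) {
    stopifnot_same_grid(mri_input, ct_input, "MRI and CT inputs")
    mrv <- mri_input$voxels
    dim(mrv) <- c(dim(mrv), 1L)
  }
  dim(ctv) <- c(dim(ctv), 1L)
  r <- with_tape(nd_sunet_forward(ctv, mrv, model$params, model$config))
  pred <- r$root$val
  dim(pred) <- dim(ct_input$voxels)
  volume(pred, ct_input$spacing, modality = "MASK", units = "arbitrary",
         origin = ct_input$origin, orientation = ct_input$orientation)
}
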