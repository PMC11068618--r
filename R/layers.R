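# 3D network layers on the autodiff tape.
#
# Feature maps are single-sample arrays laid out (X, Y, Z, C); batching
# is done by accumulating gradients across samples.  Convolutions use
# im2col + BLAS GEMM with zero padding; the scatter in the backward pass
# is a precomputed sparse matrix product.  Index caches are keyed by
# grid shape so repeated training iterations pay the setup cost once.

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  v <- builder()
  assign(key, v, envir = .idx_cache)
  v
}

# column-major tap offsets of a k^3 kernel, k odd
kernel_taps <- function(k) {
  p <- (k - 1L) / 2L
  as.matrix(expand.grid(dx = -p:p, dy = -p:p, dz = -p:p))
}

# neighbour-index map of a same-padded k^3 convolution: nvox*K 1-based
# linear indices into the (unpadded) grid, 0 for out-of-grid (zero pad)
conv_cache <- function(d, k) {
  key <- paste("conv", d[1], d[2], d[3], k, sep = ".")
  cache_get(key, function() {
    ii <- rep(seq_len(d[1]), times = d[2] * d[3])
    jj <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
    kk <- rep(seq_len(d[3]), each = d[1] * d[2])
    taps <- kernel_taps(k)
    K <- nrow(taps)
    nvox <- prod(d)
    M <- integer(nvox * K)
    for (t in seq_len(K)) {
      qi <- ii + taps[t, 1]; qj <- jj + taps[t, 2]; qk <- kk + taps[t, 3]
      ok <- qi >= 1L & qi <= d[1] & qj >= 1L & qj <= d[2] &
        qk >= 1L & qk <= d[3]
      lin <- qi + (qj - 1L) * d[1] + (qk - 1L) * d[1] * d[2]
      lin[!ok] <- 0L
      M[(t - 1L) * nvox + seq_len(nvox)] <- lin
    }
    list(M = M)
  })
}

# same-padded 3D convolution; W: (k^3 * Cin) x Cout, b: length Cout
nd_conv3d <- function(x, W, b, k = 3L) {
  wn <- nd_param(W); bn <- nd_param(b)
  d <- dim(x$val)
  sp <- d[1:3]; Cin <- d[4]
  cc <- conv_cache(sp, k)
  nvox <- prod(sp)
  xm <- x$val; dim(xm) <- c(nvox, Cin)
  outm <- cpp_conv_fwd(xm, cc$M, k^3, wn$val, bn$val)
  Cout <- ncol(outm)
  out <- outm; dim(out) <- c(sp, Cout)
  nd_node(out, list(x, wn, bn), function(self) {
    g <- self$grad; dim(g) <- c(nvox, Cout)
    bw <- cpp_conv_bwd(xm, cc$M, k^3, wn$val, g)
    dx <- bw$dx
    dim(dx) <- d
    list(dx, bw$dW, bw$db)
  })
}

pool_cache <- function(fine) {
  key <- paste("pool", fine[1], fine[2], fine[3], sep = ".")
  cache_get(key, function() {
    stopifnot(all(fine %% 2L == 0L))
    coarse <- fine %/% 2L
    nout <- prod(coarse)
    ai <- rep(seq_len(coarse[1]), times = coarse[2] * coarse[3])
    bj <- rep(rep(seq_len(coarse[2]), each = coarse[1]), times = coarse[3])
    ck <- rep(seq_len(coarse[3]), each = coarse[1] * coarse[2])
    Cidx <- matrix(0L, nout, 8L)
    t <- 0L
    for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
      t <- t + 1L
      Cidx[, t] <- (2L * ai - 1L + ox) +
        (2L * bj - 2L + oy) * fine[1] +
        (2L * ck - 2L + oz) * fine[1] * fine[2]
    }
    list(Cidx = Cidx, coarse = coarse)
  })
}

# 2x2x2 max pooling (requires even spatial dims)
nd_maxpool2 <- function(x) {
  d <- dim(x$val)
  pc <- pool_cache(d[1:3])
  nout <- nrow(pc$Cidx); C <- d[4]
  xm <- x$val; dim(xm) <- c(prod(d[1:3]), C)
  vals <- xm[as.vector(pc$Cidx), , drop = FALSE]
  dim(vals) <- c(nout, 8L, C)
  cur <- vals[, 1L, ]; dim(cur) <- c(nout, C)
  arg <- matrix(1L, nout, C)
  for (j in 2:8) {
    vj <- vals[, j, ]; dim(vj) <- c(nout, C)
    upd <- vj > cur
    cur[upd] <- vj[upd]
    arg[upd] <- j
  }
  out <- cur; dim(out) <- c(pc$coarse, C)
  nd_node(out, list(x), cache = arg, function(self) {
    g <- self$grad; dim(g) <- c(nout, C)
    dx <- matrix(0, prod(d[1:3]), C)
    a <- self$cache
    for (ch in seq_len(C)) {
      tgt <- pc$Cidx[cbind(seq_len(nout), a[, ch])]
      dx[tgt, ch] <- g[, ch]
    }
    dim(dx) <- d
    list(dx)
  })
}

# nearest-neighbour 2x upsampling to `fine` spatial dims
nd_upsample2 <- function(x, fine) {
  d <- dim(x$val)
  stopifnot(all(fine == 2L * d[1:3]))
  pc <- pool_cache(fine)
  C <- d[4]
  xm <- x$val; dim(xm) <- c(prod(d[1:3]), C)
  out <- matrix(0, prod(fine), C)
  for (j in 1:8) out[pc$Cidx[, j], ] <- xm
  dim(out) <- c(fine, C)
  nd_node(out, list(x), function(self) {
    g <- self$grad; dim(g) <- c(prod(fine), C)
    dx <- matrix(0, prod(d[1:3]), C)
    for (j in 1:8) dx <- dx + g[pc$Cidx[, j], , drop = FALSE]
    dim(dx) <- d
    list(dx)
  })
}

## ---- deformable sampling --------------------------------------------------

base_coords <- function(d) {
  key <- paste("coords", d[1], d[2], d[3], sep = ".")
  cache_get(key, function() {
    list(x = rep(seq_len(d[1]), times = d[2] * d[3]),
         y = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
         z = rep(seq_len(d[3]), each = d[1] * d[2]))
  })
}

# Sample the input at deformed kernel-tap positions.  `off` holds, per
# voxel, 3*K offsets in voxel units (x,y,z for each of the K taps, tap-
# major).  Output: (nvox, K, C) patch tensor; zero outside the grid.
# All taps are processed together so the 8 trilinear corners become 8
# large gathers/scatters instead of 8*K small ones.
nd_defsample <- function(x, off, k = 3L) {
  d <- dim(x$val); sp <- d[1:3]; C <- d[4]
  nvox <- prod(sp); K <- k^3
  taps <- kernel_taps(k)
  bc <- base_coords(sp)
  xm <- x$val; dim(xm) <- c(nvox, C)
  offm <- off$val; dim(offm) <- c(nvox, 3L * K)
  xs <- seq.int(1L, 3L * K, by = 3L)
  PX <- matrix(bc$x, nvox, K) + rep(taps[, 1], each = nvox) + offm[, xs]
  PY <- matrix(bc$y, nvox, K) + rep(taps[, 2], each = nvox) + offm[, xs + 1L]
  PZ <- matrix(bc$z, nvox, K) + rep(taps[, 3], each = nvox) + offm[, xs + 2L]
  patches <- cpp_defsample_fwd(xm, PX, PY, PZ, as.integer(sp))
  dim(patches) <- c(nvox, K, C)
  nd_node(patches, list(x, off), function(self) {
    g <- self$grad
    dim(g) <- c(nvox, K * C)
    bw <- cpp_defsample_bwd(xm, PX, PY, PZ, g, as.integer(sp))
    doff <- matrix(0, nvox, 3L * K)
    doff[, xs] <- bw$dPX
    doff[, xs + 1L] <- bw$dPY
    doff[, xs + 2L] <- bw$dPZ
    dxm <- bw$dx
    dim(dxm) <- d
    dim(doff) <- dim(off$val)
    list(dxm, doff)
  })
}

# patch tensor (nvox, K, C) times weights (K*C) x Cout -> feature map
nd_patchmm <- function(pat, W, b, sp) {
  wn <- nd_param(W); bn <- nd_param(b)
  dp <- dim(pat$val)
  nvox <- dp[1]; KC <- dp[2] * dp[3]
  pm <- pat$val; dim(pm) <- c(nvox, KC)
  outm <- pm %*% wn$val
  outm <- sweep(outm, 2L, bn$val, `+`)
  Cout <- ncol(outm)
  out <- outm; dim(out) <- c(sp, Cout)
  nd_node(out, list(pat, wn, bn), function(self) {
    g <- self$grad; dim(g) <- c(nvox, Cout)
    dW <- crossprod(pm, g)
    db <- colSums(g)
    dpat <- g %*% t(wn$val)
    dim(dpat) <- dp
    list(dpat, dW, db)
  })
}

## ---- parameter constructors ----------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

conv_params <- function(cin, cout, k = 3L) {
  list(W = param_new(he_init(k^3 * cin, cout, k^3 * cin)),
       b = param_new(numeric(cout)))
}

#' Squeeze-and-excite parameters
#'
#' @param channels channel count C of the feature map.
#' @param reduction bottleneck reduction ratio r; the hidden width is
#'   `max(1, C / r)`.
#' @return list of dense-layer parameter containers.
#' @export
se_params <- function(channels, reduction = 4) {
  hid <- max(1L, as.integer(channels / reduction))
  list(W1 = param_new(he_init(channels, hid, channels)),
       b1 = param_new(numeric(hid)),
       W2 = param_new(he_init(hid, channels, hid)),
       b2 = param_new(numeric(channels)),
       channels = channels, reduction = reduction)
}

#' Deformable convolution parameters
#'
#' The offset-predicting convolution is initialised to zero so the layer
#' starts as a standard convolution; the main kernel uses He
#' initialisation.
#'
#' @param cin,cout input/output channel counts.
#' @param k odd kernel size of the deformable kernel.
#' @param k_off odd kernel size of the offset-predicting convolution
#'   (default 1: offsets are predicted pointwise from the local feature
#'   vector, which keeps the block light).
#' @return parameter list (`Woff`, `boff`, `Wmain`, `bmain`, `k`).
#' @export
defconv_params <- function(cin, cout = cin, k = 3L, k_off = 1L) {
  K <- k^3
  list(Woff = param_new(matrix(0, k_off^3 * cin, 3L * K)),
       boff = param_new(numeric(3L * K)),
       Wmain = param_new(he_init(K * cin, cout, K * cin)),
       bmain = param_new(numeric(cout)),
       k = k, k_off = k_off)
}

#' Force a deformable convolution to the identity map
#'
#' Sets all offset-predicting weights to zero and the main kernel to a
#' centre-tap identity, so the layer reproduces its input exactly.
#'
#' @param params a [defconv_params()] list with `cin == cout`.
#' @return the modified parameter list, invisibly usable in place (the
#'   containers are environments).
#' @export
defconv_identity <- function(params) {
  K <- params$k^3
  cio <- dim(params$Wmain$value)
  cin <- cio[1] / K; cout <- cio[2]
  stopifnot(cin == cout)
  params$Woff$value[] <- 0
  params$boff$value[] <- 0
  W <- matrix(0, K * cin, cout)
  centre <- (K + 1L) / 2L
  for (c in seq_len(cin)) W[centre + K * (c - 1L), c] <- 1
  params$Wmain$value <- W
  params$bmain$value[] <- 0
  invisible(params)
}

## ---- composite blocks (tape) ----------------------------------------------

nd_se <- function(x, pars) {
  g <- nd_gap(x)
  h <- nd_relu(nd_dense(g, pars$W1, pars$b1))
  s <- nd_sigmoid(nd_dense(h, pars$W2, pars$b2))
  nd_chanscale(x, s)
}

nd_defconv <- function(x, pars) {
  sp <- dim(x$val)[1:3]
  off <- nd_conv3d(x, pars$Woff, pars$boff, k = pars$k_off)
  pat <- nd_defsample(x, off, k = pars$k)
  nd_patchmm(pat, pars$Wmain, pars$bmain, sp)
}

# Modality attention: deformably align MRI features to CT, derive a
# per-channel softmax gate from the pooled sum, gate both streams and
# add them.  Returns a list so callers can inspect intermediates.
nd_modality_attention <- function(z_mri, z_ct, pars) {
  z_tran <- nd_defconv(z_mri, pars$defconv)
  z_mrict <- nd_add(z_ct, z_tran)
  z_gp <- nd_gap(z_mrict)
  w <- nd_softmax(z_gp)
  z_ctatt <- nd_chanscale(z_ct, w)
  z_mriatt <- nd_chanscale(z_tran, w)
  list(out = nd_add(z_ctatt, z_mriatt), weights = w, z_tran = z_tran,
       z_mrict = z_mrict, z_gp = z_gp)
}

ma_params <- function(channels, k = 3L) {
  list(defconv = defconv_params(channels, channels, k = k))
}

## ---- exported functional wrappers -----------------------------------------

as_featuremap <- function(z) {
  if (length(dim(z)) == 3L) dim(z) <- c(dim(z), 1L)
  if (length(dim(z)) != 4L) stop("feature map must be a 3D or 4D array (X,Y,Z,C)")
  z
}

#' Global average pooling of a 3D feature map
#'
#' Per channel, the arithmetic mean over all `W*H*D` spatial positions.
#'
#' @param z array (X, Y, Z, C) (3D arrays are treated as one channel).
#' @return numeric vector of length C.
#' @export
global_average_pool <- function(z) {
  z <- as_featuremap(z)
  d <- dim(z)
  m <- z; dim(m) <- c(prod(d[1:3]), d[4])
  colMeans(m)
}

#' 3D squeeze-and-excite block
#'
#' Rescales each channel by a gate in (0,1): global average pooling,
#' a two-layer bottleneck (`C -> C/r -> C`) with ReLU, and a sigmoid.
#'
#' @param z feature map array (X, Y, Z, C).
#' @param reduction bottleneck ratio (ignored when `params` given).
#' @param params optional [se_params()]; freshly initialised otherwise.
#' @return array of the same shape as `z`.
#' @export
se_block_3d <- function(z, reduction = 4, params = NULL) {
  z <- as_featuremap(z)
  if (is.null(params)) params <- se_params(dim(z)[4], reduction)
  r <- with_tape(nd_se(nd_const(z), params))
  r$root$val
}

#' 3D deformable convolution
#'
#' A convolution whose sampling grid is displaced by learned per-voxel,
#' per-tap 3D offsets (in voxel units), applied with trilinear
#' interpolation.  Offsets are predicted by a sibling convolution and
#' trained jointly with the kernel weights.
#'
#' @param z feature map array (X, Y, Z, C).
#' @param params optional [defconv_params()]; freshly initialised
#'   otherwise (zero offsets).
#' @param kernel odd kernel size when `params` is NULL.
#' @return array (X, Y, Z, Cout).
#' @export
deformable_conv_3d <- function(z, params = NULL, kernel = 3L) {
  z <- as_featuremap(z)
  if (is.null(params)) params <- defconv_params(dim(z)[4], dim(z)[4], k = kernel)
  r <- with_tape(nd_defconv(nd_const(z), params))
  r$root$val
}

#' Modality-attention fusion of MRI and CT feature maps
#'
#' Implements, in order: deformable alignment of the MRI features,
#' elementwise sum with the CT features, global average pooling of the
#' sum, a softmax over the channel axis giving per-channel attention
#' weights, gating of both streams by those weights, and their sum as
#' the fused encoder output.
#'
#' @param z_mri,z_ct feature maps (X, Y, Z, C) of identical shape.
#' @param params optional [ma_params()] parameter list.
#' @return list with `z_encoder`, `weights` (softmax, sums to 1),
#'   `z_mri_tran` and `z_mrict`.
#' @export
modality_attention <- function(z_mri, z_ct, params = NULL) {
  z_mri <- as_featuremap(z_mri); z_ct <- as_featuremap(z_ct)
  if (!identical(dim(z_mri), dim(z_ct))) stop("shape mismatch between MRI and CT feature maps")
  if (is.null(params)) params <- ma_params(dim(z_mri)[4])
  r <- with_tape(nd_modality_attention(nd_const(z_mri), nd_const(z_ct), params))
  list(z_encoder = r$root$out$val, weights = r$root$weights$val,
       z_mri_tran = r$root$z_tran$val, z_mrict = r$root$z_mrict$val)
}
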