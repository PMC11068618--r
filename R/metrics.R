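# Spacing-aware contour evaluation: DSC (%), average surface distance
# (mm) and Hausdorff-95 (mm).  Surfaces are the centres of mask voxels
# with at least one six-connected background neighbour (voxels on the
# grid boundary count as surface).  Distances use an exact anisotropic
# Euclidean distance transform (separable lower-envelope algorithm), so
# they agree with an all-pairs nearest-point computation.

# 1D squared-distance transform along one axis (Felzenszwalb-style
# parabola envelope); f holds squared distances so far, w2 the squared
# voxel spacing along this axis.
dt1d <- function(f, w2) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(rep(Inf, n))
  v <- integer(length(fin))
  z <- numeric(length(fin) + 1L)
  k <- 1L
  v[1L] <- fin[1L]
  z[1L] <- -Inf
  z[2L] <- Inf
  if (length(fin) > 1L) {
    for (qi in 2:length(fin)) {
      q <- fin[qi]
      repeat {
        vk <- v[k]
        s <- ((f[q] + q * q * w2) - (f[vk] + vk * vk * w2)) /
          (2 * w2 * (q - vk))
        if (k > 1L && s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  d <- numeric(n)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < q) j <- j + 1L
    d[q] <- (q - v[j])^2 * w2 + f[v[j]]
  }
  d
}

# exact squared Euclidean distance (mm^2) to the nearest TRUE voxel
edt_sq <- function(seed, spacing) {
  d <- dim(seed)
  f <- array(ifelse(seed, 0, Inf), d)
  # axis 1
  m <- f; dim(m) <- c(d[1], d[2] * d[3])
  m <- apply(m, 2L, dt1d, w2 = spacing[1]^2)
  dim(m) <- d
  # axis 2
  m <- aperm(m, c(2, 1, 3))
  mm <- m; dim(mm) <- c(d[2], d[1] * d[3])
  mm <- apply(mm, 2L, dt1d, w2 = spacing[2]^2)
  dim(mm) <- c(d[2], d[1], d[3])
  m <- aperm(mm, c(2, 1, 3))
  # axis 3
  m <- aperm(m, c(3, 1, 2))
  mm <- m; dim(mm) <- c(d[3], d[1] * d[2])
  mm <- apply(mm, 2L, dt1d, w2 = spacing[3]^2)
  dim(mm) <- c(d[3], d[1], d[2])
  aperm(mm, c(2, 3, 1))
}

shift_array <- function(x, axis, by, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    idx_dst[[axis]] <- (by + 1):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

surface_mask <- function(mask) {
  m <- as_array3d(mask) > 0.5
  if (!any(m)) stop("undefined surface: empty mask")
  interior <- array(TRUE, dim(m))
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    interior <- interior & shift_array(m, axis, by, fill = FALSE)
  }
  m & !interior
}

#' Surface voxels of a binary mask
#'
#' Returns the centres (in mm) of mask voxels that touch background
#' under six-connectivity; voxels on the grid boundary are surface.
#'
#' @param mask binary mask (`volume` or array).
#' @param spacing voxel spacing in mm (taken from the volume if given).
#' @param origin physical origin (mm) of voxel (1,1,1).
#' @return n x 3 matrix of physical coordinates in mm.
#' @export
surface_voxels <- function(mask, spacing = NULL, origin = c(0, 0, 0)) {
  if (is_volume(mask)) {
    spacing <- mask$spacing
    origin <- mask$origin
  }
  if (is.null(spacing)) stop("spacing required for array masks")
  sm <- surface_mask(mask)
  idx <- which(sm, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2L, spacing, `*`), 2L, origin, `+`)
}

metric_spacing <- function(pred, gt, spacing) {
  if (is_volume(pred)) spacing <- pred$spacing
  if (is.null(spacing)) stop("spacing required for array masks")
  spacing
}

# directed nearest-surface distances pred->gt and gt->pred (mm)
directed_surface_distances <- function(pred, gt, spacing = NULL) {
  spacing <- metric_spacing(pred, gt, spacing)
  p <- as_array3d(pred) > 0.5
  g <- as_array3d(gt) > 0.5
  stopifnot_same_grid(p, g, "pred and gt")
  if (!any(p) || !any(g)) stop("surface distances undefined for an empty mask")
  sp_ <- surface_mask(p)
  sg_ <- surface_mask(g)
  Dg <- sqrt(edt_sq(sg_, spacing))
  Dp <- sqrt(edt_sq(sp_, spacing))
  list(pred_to_gt = Dg[sp_], gt_to_pred = Dp[sg_])
}

#' Dice similarity coefficient (percent)
#'
#' `100 * 2|P intersect G| / (|P| + |G|)`; defined as 100 when both
#' masks are empty.
#'
#' @param pred,gt binary masks on one grid (`volume` or array).
#' @return DSC in \[0, 100\].
#' @export
dsc <- function(pred, gt) {
  p <- as_array3d(pred) > 0.5
  g <- as_array3d(gt) > 0.5
  stopifnot_same_grid(p, g, "pred and gt")
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0) return(100)
  100 * 2 * sum(p & g) / (np + ng)
}

#' Average surface distance (mm)
#'
#' Symmetric: the mean over the pooled set of directed nearest-surface
#' distances (every pred-surface point to its nearest gt-surface point
#' and vice versa).
#'
#' @inheritParams dsc
#' @param spacing voxel spacing in mm for array inputs.
#' @return ASD in mm.
#' @export
asd <- function(pred, gt, spacing = NULL) {
  ds <- directed_surface_distances(pred, gt, spacing)
  mean(c(ds$pred_to_gt, ds$gt_to_pred))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' By default the 95th percentile (linear interpolation) of the pooled
#' directed nearest-surface distances; `convention = "max_directed"`
#' takes the maximum of the two per-direction percentiles instead.
#'
#' @inheritParams asd
#' @param convention `"pooled"` (default) or `"max_directed"`.
#' @param probs percentile in (0,1\]; default 0.95.
#' @return HD95 in mm.
#' @export
hd95 <- function(pred, gt, spacing = NULL,
                 convention = c("pooled", "max_directed"), probs = 0.95) {
  convention <- match.arg(convention)
  ds <- directed_surface_distances(pred, gt, spacing)
  if (convention == "pooled") {
    unname(stats::quantile(c(ds$pred_to_gt, ds$gt_to_pred), probs, type = 7))
  } else {
    max(stats::quantile(ds$pred_to_gt, probs, type = 7),
        stats::quantile(ds$gt_to_pred, probs, type = 7))
  }
}

#' Full segmentation metrics report
#'
#' @inheritParams asd
#' @return list with `dsc_percent`, `asd_mm`, `hd95_mm`,
#'   `n_pred_voxels`, `n_gt_voxels` and `status` (`"ok"` or
#'   `"undefined"` when either mask is empty, in which case the surface
#'   metrics are `NA` rather than infinite).
#' @export
evaluate_segmentation <- function(pred, gt, spacing = NULL) {
  p <- as_array3d(pred) > 0.5
  g <- as_array3d(gt) > 0.5
  stopifnot_same_grid(p, g, "pred and gt")
  out <- list(dsc_percent = dsc(p, g), asd_mm = NA_real_, hd95_mm = NA_real_,
              n_pred_voxels = sum(p), n_gt_voxels = sum(g), status = "ok")
  if (!any(p) || !any(g)) {
    out$status <- "undefined"
    return(out)
  }
  spacing <- metric_spacing(pred, gt, spacing)
  ds <- directed_surface_distances(p, g, spacing)
  pooled <- c(ds$pred_to_gt, ds$gt_to_pred)
  out$asd_mm <- mean(pooled)
  out$hd95_mm <- unname(stats::quantile(pooled, 0.95, type = 7))
  out
}
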