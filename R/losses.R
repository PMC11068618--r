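#' Hounsfield-unit tissue window
#'
#' Inclusive HU interval defining a tissue class on raw CT.  Defaults
#' follow the windows used by the muscle/bone inclusion losses: muscle
#' `[-29, 150]` HU, bone `[300, 1200]` HU.
#'
#' @param low,high window bounds in HU (`low < high`, both inclusive).
#' @param tissue `"muscle"` or `"bone"`.
#' @return list of class `hu_window`.
#' @export
hu_window <- function(low, high, tissue = c("muscle", "bone")) {
  tissue <- match.arg(tissue)
  stopifnot(is.finite(low), is.finite(high), low < high)
  structure(list(low = low, high = high, tissue = tissue), class = "hu_window")
}

#' @rdname hu_window
#' @export
muscle_window <- function() hu_window(-29, 150, "muscle")

#' @rdname hu_window
#' @export
bone_window <- function() hu_window(300, 1200, "bone")

#' Threshold raw CT with a tissue window
#'
#' Mask is true exactly where `low <= HU <= high` (both bounds
#' inclusive).  Thresholds always apply to raw HU, never to normalised
#' intensities.
#'
#' @param ct_raw_hu CT [volume()] in HU (or a plain HU array).
#' @param window an [hu_window()].
#' @return binary mask `volume` (or array if the input was an array).
#' @export
threshold_ct <- function(ct_raw_hu, window) {
  stopifnot(inherits(window, "hu_window"))
  if (is_volume(ct_raw_hu)) {
    if (ct_raw_hu$units != "HU") stop("tissue windows apply to raw HU volumes only")
    m <- ct_raw_hu$voxels >= window$low & ct_raw_hu$voxels <= window$high
    return(binary_mask(array(as.numeric(m), dim(m)), ct_raw_hu$spacing,
                       origin = ct_raw_hu$origin))
  }
  m <- ct_raw_hu >= window$low & ct_raw_hu <= window$high
  array(as.numeric(m), dim(ct_raw_hu))
}

#' Loss weights of the combined objective
#'
#' @param wm weight of the muscle inclusion loss (default 0.1).
#' @param wb weight of the bone inclusion loss (default 0.01).
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(wm = 0.1, wb = 0.01) {
  stopifnot(wm >= 0, wb >= 0)
  structure(list(wm = wm, wb = wb), class = "loss_weights")
}

#' Soft Dice segmentation loss
#'
#' `1 - (2 sum(p g) + eps) / (sum(p) + sum(g) + eps)` for the default
#' `"dice"` form; the `"jaccard"` form uses the union denominator
#' `sum(p) + sum(g) - sum(p g)`.  Defined on soft probabilities so it is
#' differentiable; on binary inputs it reduces to the set formula.
#'
#' @param pred probability map (array or `volume`), values in \[0,1\].
#' @param gt binary ground-truth mask on the same grid.
#' @param eps smoothing constant added to numerator and denominator.
#' @param form `"dice"` (default) or `"jaccard"`.
#' @return scalar loss in \[0,1\].
#' @export
dsc_loss <- function(pred, gt, eps = 1e-5, form = c("dice", "jaccard")) {
  form <- match.arg(form)
  p <- as_array3d(pred); g <- as_array3d(gt)
  stopifnot_same_grid(p, g, "pred and gt")
  inter <- sum(p * g)
  if (form == "dice") {
    1 - (2 * inter + eps) / (sum(p) + sum(g) + eps)
  } else {
    1 - (inter + eps) / (sum(p) + sum(g) - inter + eps)
  }
}

#' Tissue inclusion loss
#'
#' The fraction of predicted probability mass lying inside a tissue
#' mask: `(sum(p * tissue) + eps) / (sum(p) + eps)`.  Used
#' self-supervised against HU-thresholded raw CT to discourage
#' predictions from leaking into muscle or bone when labels are noisy.
#'
#' @param pred probability map.
#' @param tissue binary tissue mask on the same grid (e.g. from
#'   [threshold_ct()]).
#' @param eps smoothing constant.
#' @return scalar in \[0,1\].
#' @export
inclusion_loss <- function(pred, tissue, eps = 1e-5) {
  p <- as_array3d(pred); tis <- as_array3d(tissue)
  stopifnot_same_grid(p, tis, "pred and tissue mask")
  (sum(p * tis) + eps) / (sum(p) + eps)
}

#' Combined training objective
#'
#' `dsc_loss + wm * inclusion_loss(pred, muscle) + wb *
#' inclusion_loss(pred, bone)`, with the tissue masks obtained by
#' thresholding the *raw* HU volume with the muscle and bone windows.
#'
#' @param pred probability map.
#' @param gt binary ground-truth mask.
#' @param ct_raw_hu raw CT volume in HU on the same grid.
#' @param weights a [loss_weights()].
#' @param muscle,bone [hu_window()]s for the two tissues.
#' @inheritParams dsc_loss
#' @return scalar loss in `[0, 1 + wm + wb]`.
#' @export
combined_loss <- function(pred, gt, ct_raw_hu, weights = loss_weights(),
                          muscle = muscle_window(), bone = bone_window(),
                          eps = 1e-5, form = c("dice", "jaccard")) {
  form <- match.arg(form)
  mm <- as_array3d(threshold_ct(ct_raw_hu, muscle))
  bm <- as_array3d(threshold_ct(ct_raw_hu, bone))
  dsc_loss(pred, gt, eps = eps, form = form) +
    weights$wm * inclusion_loss(pred, mm, eps = eps) +
    weights$wb * inclusion_loss(pred, bm, eps = eps)
}

## ---- tape versions (used by training) -------------------------------------

nd_dsc_loss <- function(pred, g, eps = 1e-5, form = "dice") {
  dim(g) <- dim(pred$val)
  inter <- nd_sum(nd_mul(pred, nd_const(g)))
  sp <- nd_sum(pred)
  sg <- sum(g)
  if (form == "dice") {
    num <- nd_shift(nd_scale(inter, 2), eps)
    den <- nd_shift(sp, sg + eps)
  } else {
    num <- nd_shift(inter, eps)
    den <- nd_shift(nd_sub(sp, inter), sg + eps)
  }
  nd_shift(nd_scale(nd_div(num, den), -1), 1)
}

nd_inclusion_loss <- function(pred, tissue, eps = 1e-5) {
  dim(tissue) <- dim(pred$val)
  num <- nd_shift(nd_sum(nd_mul(pred, nd_const(tissue))), eps)
  den <- nd_shift(nd_sum(pred), eps)
  nd_div(num, den)
}

nd_combined_loss <- function(pred, g, muscle_mask, bone_mask,
                             weights = loss_weights(), eps = 1e-5,
                             form = "dice") {
  l <- nd_dsc_loss(pred, g, eps = eps, form = form)
  if (weights$wm > 0) {
    l <- nd_add(l, nd_scale(nd_inclusion_loss(pred, muscle_mask, eps), weights$wm))
  }
  if (weights$wb > 0) {
    l <- nd_add(l, nd_scale(nd_inclusion_loss(pred, bone_mask, eps), weights$wb))
  }
  l
}
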