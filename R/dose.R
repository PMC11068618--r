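# Dosimetric evaluation of a contour under a fixed planned dose grid:
# mean structure dose (Dmean, Gy) and the volume fraction receiving at
# least 20 Gy (V20, % of structure volume; the threshold is inclusive).

check_dose <- function(dose, mask) {
  dv <- as_array3d(dose)
  mv <- as_array3d(mask) > 0.5
  stopifnot_same_grid(dv, mv, "dose and mask")
  if (is_volume(dose) && dose$modality != "DOSE") {
    stop("dose grid must have modality DOSE (Gy)")
  }
  if (any(dv < 0) || any(!is.finite(dv))) stop("dose values must be finite and >= 0")
  if (!any(mv)) stop("empty mask: dose statistics undefined")
  list(dose = dv, mask = mv)
}

#' Mean structure dose (Gy)
#'
#' Arithmetic mean dose over the voxels of a structure mask.
#'
#' @param dose dose grid in Gy (`volume` or array).
#' @param mask nonempty binary structure mask on the same grid.
#' @return Dmean in Gy.
#' @export
dmean <- function(dose, mask) {
  x <- check_dose(dose, mask)
  mean(x$dose[x$mask])
}

#' Volume receiving at least a threshold dose (percent)
#'
#' `100 * #(mask voxels with dose >= threshold) / #(mask voxels)`.
#'
#' @inheritParams dmean
#' @param threshold_gy dose threshold in Gy (inclusive; default 20).
#' @return percent of structure volume in \[0, 100\].
#' @export
v20 <- function(dose, mask, threshold_gy = 20) {
  x <- check_dose(dose, mask)
  100 * sum(x$dose[x$mask] >= threshold_gy) / sum(x$mask)
}

#' Per-structure dose report
#'
#' @inheritParams v20
#' @param spacing voxel spacing in mm (taken from the volume if given);
#'   used for the structure volume in cm^3.
#' @return list with `dmean_gy`, `v20_percent`, `v20_cc` (absolute
#'   volume at or above threshold) and `structure_volume_cc`.
#' @export
dose_report <- function(dose, mask, threshold_gy = 20, spacing = NULL) {
  x <- check_dose(dose, mask)
  if (is_volume(mask)) spacing <- mask$spacing
  if (is.null(spacing) && is_volume(dose)) spacing <- dose$spacing
  vox_cc <- if (is.null(spacing)) NA_real_ else prod(spacing) / 1000
  n <- sum(x$mask)
  nhot <- sum(x$dose[x$mask] >= threshold_gy)
  list(dmean_gy = mean(x$dose[x$mask]),
       v20_percent = 100 * nhot / n,
       v20_cc = nhot * vox_cc,
       structure_volume_cc = n * vox_cc)
}

#' Compare two contours under one dose grid
#'
#' Reports Dmean/V20 per contour plus paired differences `a - b`,
#' absolute and as a percentage of contour `a`'s value.
#'
#' @inheritParams dose_report
#' @param mask_a,mask_b nonempty binary masks on the dose grid (e.g.
#'   reference and predicted contours).
#' @return list with elements `a`, `b` (each a [dose_report()]) and
#'   `diff` (`dmean_gy`, `v20_percent`, and `*_relpct` relative to `a`).
#' @export
compare_contours <- function(dose, mask_a, mask_b, threshold_gy = 20,
                             spacing = NULL) {
  ra <- dose_report(dose, mask_a, threshold_gy, spacing)
  rb <- dose_report(dose, mask_b, threshold_gy, spacing)
  relpct <- function(d, ref) if (ref == 0) NA_real_ else 100 * d / ref
  diff <- list(
    dmean_gy = ra$dmean_gy - rb$dmean_gy,
    dmean_relpct = relpct(ra$dmean_gy - rb$dmean_gy, ra$dmean_gy),
    v20_percent = ra$v20_percent - rb$v20_percent,
    v20_relpct = relpct(ra$v20_percent - rb$v20_percent, ra$v20_percent)
  )
  list(a = ra, b = rb, diff = diff)
}
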