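#' 3D scalar volumes with physical spacing
#'
#' A `volume` is the package's basic container: a 3D numeric array plus
#' per-axis voxel spacing in millimetres, a modality tag and a unit tag.
#' CT volumes carry calibrated Hounsfield units (HU), MRI volumes carry
#' arbitrary units, dose grids carry Gy and masks are binary.  Voxel
#' indices are 1-based in R; the physical position of voxel `(i,j,k)` is
#' `origin + (c(i,j,k) - 1) * spacing` (voxel-centred convention).
#'
#' @param voxels 3D numeric array (W x H x D).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param modality one of `"CT"`, `"MRI"`, `"DOSE"`, `"MASK"`.
#' @param units unit tag; defaults to the conventional unit of the
#'   modality (`"HU"`, `"arbitrary"`, `"Gy"`, `"binary"`).
#' @param origin physical position (mm) of the first voxel centre.
#' @param orientation optional axis-orientation code string (e.g. `"RAS"`)
#'   recorded from a NIfTI header; purely informative.
#' @return An object of class `volume`.
#' @export
volume <- function(voxels, spacing, modality = c("CT", "MRI", "DOSE", "MASK"),
                   units = NULL, origin = c(0, 0, 0), orientation = NA_character_) {
  modality <- match.arg(modality)
  if (is.null(units)) {
    units <- switch(modality, CT = "HU", MRI = "arbitrary",
                    DOSE = "Gy", MASK = "binary")
  }
  if (is.logical(voxels)) voxels <- array(as.numeric(voxels), dim(voxels))
  if (length(dim(voxels)) != 3L) stop("non-3D image: voxels must be a 3D array")
  if (!all(is.finite(voxels))) stop("volume contains non-finite voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive values (mm)")
  }
  if (modality == "CT" && units == "HU" &&
      (min(voxels) < -1024 || max(voxels) > 3072)) {
    stop("CT voxels outside the plausible HU range [-1024, 3072]")
  }
  if (modality == "DOSE" && min(voxels) < 0) {
    stop("dose grid contains negative values")
  }
  structure(list(voxels = voxels, spacing = spacing, modality = modality,
                 units = units, origin = as.numeric(origin),
                 orientation = orientation),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume> %s [%s]  %d x %d x %d  spacing %.3g x %.3g x %.3g mm\n",
              x$modality, x$units, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$voxels)

is_volume <- function(x) inherits(x, "volume")

stopifnot_same_grid <- function(a, b, what = "volumes") {
  da <- if (is_volume(a)) dim(a$voxels) else dim(a)
  db <- if (is_volume(b)) dim(b$voxels) else dim(b)
  if (!identical(da, db)) {
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  }
  invisible(TRUE)
}

as_array3d <- function(x) if (is_volume(x)) x$voxels else x

#' Binary mask on a volume grid
#'
#' Thin wrapper around [volume()] that coerces voxels to {0,1} and tags
#' the result as a mask.
#'
#' @param voxels logical or 0/1 numeric 3D array.
#' @inheritParams volume
#' @return A `volume` with modality `"MASK"`, units `"binary"`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  v <- as_array3d(voxels)
  if (!all(v %in% c(0, 1))) stop("mask voxels must be 0/1")
  volume(array(as.numeric(v), dim(v)), spacing, modality = "MASK",
         origin = origin)
}

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file, takes spacing from the header and
#' records the header's axis-orientation code.  The voxel array is kept
#' in the file's stored axis order; nothing is reordered silently.
#'
#' @param path path to a 3D NIfTI file.
#' @param expected_modality modality tag to attach (`"CT"`, `"MRI"`,
#'   `"DOSE"` or `"MASK"`).
#' @return A [volume()].
#' @export
read_volume <- function(path, expected_modality = c("CT", "MRI", "DOSE", "MASK")) {
  expected_modality <- match.arg(expected_modality)
  if (!file.exists(path)) stop(sprintf("missing file: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("non-3D image")
  vox <- array(as.numeric(img), d)
  if (!all(is.finite(vox))) stop("volume contains non-finite voxels")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  # the NIfTI origin is the position of voxel (1,1,1) in mm
  hdr <- RNifti::niftiHeader(img)
  origin_mm <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (!all(is.finite(origin_mm))) origin_mm <- c(0, 0, 0)
  volume(vox, sp, modality = expected_modality, origin = origin_mm,
         orientation = orient)
}

#' Write a volume to NIfTI
#'
#' Masks are stored as unsigned 8-bit {0,1}; other volumes as float32.
#'
#' @param vol a [volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  dtype <- if (vol$modality == "MASK") "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

## ---- resampling -----------------------------------------------------------

# Gather values of a multi-channel flattened grid at fractional voxel
# coordinates (1-based, continuous).  xmat: nvox x C matrix of a grid with
# dims `d`; coordinates outside the grid read as `fill`.
trilinear_gather <- function(xmat, d, ix, iy, iz, fill = 0) {
  nC <- ncol(xmat)
  n <- length(ix)
  out <- matrix(fill * 1.0, n, nC)
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  acc <- matrix(0, n, nC)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    px <- x0 + cx; py <- y0 + cy; pz <- z0 + cz
    w <- (if (cx) fx else 1 - fx) * (if (cy) fy else 1 - fy) *
      (if (cz) fz else 1 - fz)
    ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
    if (!any(ok)) next
    lin <- px + (py - 1) * d[1] + (pz - 1) * d[1] * d[2]
    lin[!ok] <- 1L
    vals <- xmat[lin, , drop = FALSE]
    wv <- w * ok
    acc <- acc + vals * wv
  }
  # renormalisation is not applied: outside contributes `fill`
  if (fill != 0) {
    # weight mass that fell outside the grid
    inw <- matrix(0, n, 1)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      px <- x0 + cx; py <- y0 + cy; pz <- z0 + cz
      w <- (if (cx) fx else 1 - fx) * (if (cy) fy else 1 - fy) *
        (if (cz) fz else 1 - fz)
      ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
      inw <- inw + w * ok
    }
    acc <- acc + (1 - inw) %*% matrix(fill, 1, nC)
  }
  out[] <- acc
  out
}

nearest_gather <- function(xvec, d, ix, iy, iz, fill = 0) {
  px <- round(ix); py <- round(iy); pz <- round(iz)
  ok <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2] & pz >= 1 & pz <= d[3]
  lin <- px + (py - 1) * d[1] + (pz - 1) * d[1] * d[2]
  lin[!ok] <- 1L
  out <- xvec[lin]
  out[!ok] <- fill
  out
}

grid_coords_mm <- function(d, spacing, origin) {
  ii <- (seq_len(d[1]) - 1) * spacing[1] + origin[1]
  jj <- (seq_len(d[2]) - 1) * spacing[2] + origin[2]
  kk <- (seq_len(d[3]) - 1) * spacing[3] + origin[3]
  list(x = rep(ii, times = d[2] * d[3]),
       y = rep(rep(jj, each = d[1]), times = d[3]),
       z = rep(kk, each = d[1] * d[2]))
}

#' Resample a volume onto another volume's grid
#'
#' Maps every voxel centre of `target` into `src`'s physical frame and
#' interpolates.  Use `"linear"` for intensities and `"nearest"` for
#' masks (nearest keeps a binary mask binary).
#'
#' @param src volume to resample.
#' @param target volume whose grid defines the output.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill value used outside `src`'s physical extent.
#' @return A `volume` on `target`'s grid with `src`'s modality/units.
#' @export
resample_to_grid <- function(src, target, interpolation = c("linear", "nearest"),
                             fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_volume(src), is_volume(target))
  ds <- dim(src$voxels); dt <- dim(target$voxels)
  # physical extents must overlap
  lo_s <- src$origin - src$spacing / 2
  hi_s <- src$origin + (ds - 1 + 0.5) * src$spacing
  lo_t <- target$origin - target$spacing / 2
  hi_t <- target$origin + (dt - 1 + 0.5) * target$spacing
  if (any(hi_s < lo_t) || any(hi_t < lo_s)) {
    stop("non-overlapping physical extents")
  }
  co <- grid_coords_mm(dt, target$spacing, target$origin)
  ix <- (co$x - src$origin[1]) / src$spacing[1] + 1
  iy <- (co$y - src$origin[2]) / src$spacing[2] + 1
  iz <- (co$z - src$origin[3]) / src$spacing[3] + 1
  if (interpolation == "linear") {
    xmat <- src$voxels; dim(xmat) <- c(prod(ds), 1L)
    vals <- trilinear_gather(xmat, ds, ix, iy, iz, fill = fill)[, 1]
  } else {
    vals <- nearest_gather(as.vector(src$voxels), ds, ix, iy, iz, fill = fill)
  }
  out <- array(vals, dt)
  volume(out, target$spacing, modality = src$modality, units = src$units,
         origin = target$origin, orientation = target$orientation)
}
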