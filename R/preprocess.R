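#' Preprocess a CT volume for the network
#'
#' Applies contrast-limited adaptive histogram equalisation (CLAHE)
#' slice-wise in the axial plane to sharpen edges, then rescales to
#' \[0,1\].  The untouched HU volume is returned alongside, because the
#' muscle/bone inclusion losses threshold *raw* HU, never the equalised
#' intensities.
#'
#' Equalisation is rank-based within tiles after a global min-max
#' rescale, so two CTs differing by a constant HU shift produce the
#' same network input.
#'
#' @param ct CT [volume()] in HU.
#' @param tile number of CLAHE tiles per in-plane axis (default 8).
#' @param clip_limit CLAHE clip limit (EBImage convention; default 2).
#' @return list with `ct_input` (equalised, \[0,1\]) and `ct_raw_hu`
#'   (verbatim copy of `ct`).
#' @export
preprocess_ct <- function(ct, tile = 8, clip_limit = 2) {
  stopifnot(is_volume(ct))
  if (ct$modality != "CT" || ct$units != "HU") {
    stop("preprocess_ct expects a CT volume in HU")
  }
  v <- ct$voxels
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) {
    warning("constant-valued CT volume; returning all-zero input")
    ct_in <- volume(array(0, dim(v)), ct$spacing, "CT", units = "arbitrary",
                    origin = ct$origin, orientation = ct$orientation)
    return(list(ct_input = ct_in, ct_raw_hu = ct))
  }
  x <- (v - rng[1]) / (rng[2] - rng[1])
  d <- dim(x)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    sl <- x[, , k]
    eq <- tryCatch(
      EBImage::clahe(sl, nx = tile, ny = tile, limit = clip_limit,
                     keep.range = FALSE),
      error = function(e) sl)
    out[, , k] <- as.numeric(eq)
  }
  out <- pmin(pmax(out, 0), 1)
  ct_in <- volume(out, ct$spacing, "CT", units = "arbitrary",
                  origin = ct$origin, orientation = ct$orientation)
  list(ct_input = ct_in, ct_raw_hu = ct)
}

#' Preprocess an MRI volume for the network
#'
#' Min-max normalisation: `(x - min) / (max - min)`, so the output spans
#' \[0,1\] exactly.
#'
#' @param mri MRI [volume()].
#' @return normalised MRI `volume` (units `"arbitrary"`).
#' @export
preprocess_mri <- function(mri) {
  stopifnot(is_volume(mri))
  if (mri$modality != "MRI") stop("preprocess_mri expects an MRI volume")
  rng <- range(mri$voxels)
  if (rng[2] - rng[1] <= 0) stop("degenerate MRI intensity range")
  out <- (mri$voxels - rng[1]) / (rng[2] - rng[1])
  volume(out, mri$spacing, "MRI", units = "arbitrary",
         origin = mri$origin, orientation = mri$orientation)
}

#' Bundle preprocessed network inputs
#'
#' Convenience constructor for the (CT input, optional MRI input, raw
#' HU, optional label) bundle consumed by training and prediction.  The
#' MRI is resampled to the CT grid if it lives on a different one.
#'
#' @param ct CT volume in HU.
#' @param mri optional MRI volume (any grid; resampled to CT's).
#' @param label optional binary mask on the CT grid.
#' @param tile,clip_limit CLAHE parameters, see [preprocess_ct()].
#' @return list of class `preprocessed_pair` with elements `ct_input`,
#'   `mri_input` (or `NULL`), `ct_raw_hu`, `label`.
#' @export
preprocess_pair <- function(ct, mri = NULL, label = NULL, tile = 8,
                            clip_limit = 2) {
  pc <- preprocess_ct(ct, tile = tile, clip_limit = clip_limit)
  mri_in <- NULL
  if (!is.null(mri)) {
    if (!identical(dim(mri$voxels), dim(ct$voxels)) ||
        any(abs(mri$spacing - ct$spacing) > 1e-9)) {
      mri <- resample_to_grid(mri, ct, interpolation = "linear")
    }
    mri_in <- preprocess_mri(mri)
  }
  if (!is.null(label)) stopifnot_same_grid(label, ct, "label and CT")
  structure(list(ct_input = pc$ct_input, mri_input = mri_in,
                 ct_raw_hu = pc$ct_raw_hu, label = label),
            class = "preprocessed_pair")
}
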