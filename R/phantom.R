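# Seeded synthetic pelvic phantoms: two thin tubular "vessels" running
# cranio-caudally through muscle, flanked by bone blocks, on a CT grid
# in HU with a higher-contrast companion MRI on its own (finer,
# misregistered) grid.  The phantoms stand in for clinical data in all
# tests: they reproduce the *properties* the method depends on -- thin
# bilateral targets near bone, muscle/bone HU context, low CT contrast
# versus high MRI contrast, residual CT-MRI misregistration, and labels
# noisily dilated into muscle and bone -- not pelvic anatomy itself.

run_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Phantom specification
#'
#' Parameters of the synthetic pelvic phantom.  Defaults encode the
#' intended tissue layout: vessel CT intensity (80 HU) sits *inside*
#' the muscle window on purpose, so the muscle-inclusion loss is in
#' genuine tension with the Dice term, as in real CT where the artery
#' is nearly isointense with muscle; bone (700 HU) and muscle (40 HU)
#' fall inside their windows; the background emulates fat.
#'
#' @param grid integer 3-vector (W, H, D) of the CT grid.
#' @param spacing CT voxel spacing in mm.
#' @param mri_spacing MRI acquisition spacing in mm (the MRI is
#'   generated on its own finer grid and resampled to CT at load time).
#' @param vessel_radius_mm tube radius.
#' @param vessel_ct_hu,vessel_mri_intensity vessel intensity per
#'   modality (MRI in \[0,1\] before noise).
#' @param bone_hu,muscle_hu,background_hu tissue intensities in HU.
#' @param mri_muscle,mri_bone,mri_background MRI tissue intensities.
#' @param noise_sigma named vector: additive Gaussian noise scale for
#'   `ct` (HU) and `mri` (intensity units).
#' @param misregistration_mm 3-vector residual MRI shift in mm.
#' @param label_noise_dilation_mm dilation of the clean label into
#'   adjacent muscle/bone to emulate noisy contours (0 = clean).
#' @param label_noise_keep probability that a voxel of the dilation
#'   shell enters the noisy label; values < 1 make the contour noise
#'   irregular and sample-specific, as hand-drawn contours are.
#' @param caudal_margin_mm caudal label extent beyond the PTV (10 mm).
#' @param muscle_halo_mm radius of the muscle sleeve around each vessel.
#' @param bone_offset_mm,bone_width_mm,bone_halfheight_mm lateral bone
#'   block geometry relative to each vessel centreline.
#' @param jitter_sd_mm smoothness scale of the vessel centreline.
#' @param seed integer seed; phantoms are bit-reproducible given it.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32L, 32L, 16L),
                         spacing = c(1.17, 1.17, 2.5),
                         mri_spacing = c(0.56, 0.56, 3),
                         vessel_radius_mm = 2,
                         vessel_ct_hu = 80,
                         vessel_mri_intensity = 0.95,
                         bone_hu = 700,
                         muscle_hu = 40,
                         background_hu = -80,
                         mri_muscle = 0.35,
                         mri_bone = 0.1,
                         mri_background = 0.2,
                         noise_sigma = c(ct = 10, mri = 0.03),
                         misregistration_mm = c(0, 0, 0),
                         label_noise_dilation_mm = 3,
                         label_noise_keep = 0.75,
                         caudal_margin_mm = 10,
                         muscle_halo_mm = 7,
                         bone_offset_mm = 3.5,
                         bone_width_mm = 6,
                         bone_halfheight_mm = 8,
                         jitter_sd_mm = 1.2,
                         seed = 1L) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid >= 8L),
            vessel_radius_mm > 0, label_noise_dilation_mm >= 0,
            bone_hu > 300, bone_hu < 1200,
            muscle_hu > -29, muscle_hu < 150)
  structure(as.list(environment()), class = "phantom_spec")
}

# smooth centreline (x(z), y(z)) in mm for one vessel
vessel_centreline <- function(x0, y0, z_mm, jitter_sd) {
  nz <- length(z_mm)
  ctrl_z <- seq(min(z_mm), max(z_mm), length.out = 5)
  cx <- x0 + stats::rnorm(5, sd = jitter_sd)
  cy <- y0 + stats::rnorm(5, sd = jitter_sd)
  list(x = stats::spline(ctrl_z, cx, xout = z_mm)$y,
       y = stats::spline(ctrl_z, cy, xout = z_mm)$y)
}

# rasterise tissue region maps for a given grid; geometry in mm,
# optionally shifted by `shift_mm` (used for the misregistered MRI)
rasterise_regions <- function(geom, d, spacing, shift_mm = c(0, 0, 0)) {
  nvox <- prod(d)
  xs <- (seq_len(d[1]) - 1) * spacing[1] - shift_mm[1]
  ys <- (seq_len(d[2]) - 1) * spacing[2] - shift_mm[2]
  zs <- (seq_len(d[3]) - 1) * spacing[3] - shift_mm[3]
  dist2 <- array(Inf, d)
  bone <- array(FALSE, d)
  for (v in geom$vessels) {
    # squared in-plane distance to the centreline point of each slice,
    # evaluated at this grid's slice heights
    cxz <- stats::approx(geom$z_mm, v$x, xout = zs, rule = 2)$y
    cyz <- stats::approx(geom$z_mm, v$y, xout = zs, rule = 2)$y
    dx2 <- outer(xs, cxz, function(a, b) (a - b)^2)   # W x D
    dy2 <- outer(ys, cyz, function(a, b) (a - b)^2)   # H x D
    for (k in seq_len(d[3])) {
      d2 <- outer(dx2[, k], dy2[, k], `+`)
      dist2[, , k] <- pmin(dist2[, , k], d2)
      bx <- if (v$side < 0) {
        xs <= v$x0 - geom$bone_offset & xs >= v$x0 - geom$bone_offset - geom$bone_width
      } else {
        xs >= v$x0 + geom$bone_offset & xs <= v$x0 + geom$bone_offset + geom$bone_width
      }
      by <- abs(ys - v$y0) <= geom$bone_halfheight
      bone[, , k] <- bone[, , k] | outer(bx, by, `&`)
    }
  }
  vessel <- dist2 <= geom$vessel_radius^2
  bone <- bone & !vessel
  muscle <- (dist2 <= geom$muscle_halo^2) & !bone & !vessel
  list(vessel = vessel, bone = bone, muscle = muscle)
}

phantom_geometry <- function(spec) {
  d <- spec$grid
  ext <- d * spec$spacing
  z_mm <- (seq_len(d[3]) - 1) * spec$spacing[3]
  xL <- 0.30 * ext[1]; xR <- 0.70 * ext[1]; yC <- 0.50 * ext[2]
  vL <- vessel_centreline(xL, yC, z_mm, spec$jitter_sd_mm)
  vR <- vessel_centreline(xR, yC, z_mm, spec$jitter_sd_mm)
  vL$x0 <- xL; vL$y0 <- yC; vL$side <- -1
  vR$x0 <- xR; vR$y0 <- yC; vR$side <- +1
  # PTV: central block cranial of the caudal end, defines label clipping
  list(vessels = list(vL, vR), z_mm = z_mm,
       vessel_radius = spec$vessel_radius_mm,
       muscle_halo = spec$muscle_halo_mm,
       bone_offset = spec$bone_offset_mm,
       bone_width = spec$bone_width_mm,
       bone_halfheight = spec$bone_halfheight_mm,
       ptv_z = c(0.40, 0.85) * ext[3],
       ptv_x = c(0.35, 0.65) * ext[1],
       ptv_y = c(0.30, 0.70) * ext[2])
}

ptv_mask <- function(geom, d, spacing) {
  xs <- (seq_len(d[1]) - 1) * spacing[1]
  ys <- (seq_len(d[2]) - 1) * spacing[2]
  zs <- (seq_len(d[3]) - 1) * spacing[3]
  m <- array(FALSE, d)
  inx <- xs >= geom$ptv_x[1] & xs <= geom$ptv_x[2]
  iny <- ys >= geom$ptv_y[1] & ys <= geom$ptv_y[2]
  inz <- zs >= geom$ptv_z[1] & zs <= geom$ptv_z[2]
  m[inx, iny, inz] <- TRUE
  m
}

#' Translate a volume by a physical offset
#'
#' Shifts the content by `offset_mm` (trilinear interpolation, edge
#' values fill the vacated border).  Used to emulate residual CT-MRI
#' misregistration.
#'
#' @param vol a [volume()].
#' @param offset_mm 3-vector shift in mm.
#' @return shifted `volume` on the same grid.
#' @export
apply_misregistration <- function(vol, offset_mm) {
  stopifnot(is_volume(vol), length(offset_mm) == 3)
  if (all(offset_mm == 0)) return(vol)
  d <- dim(vol$voxels)
  bc <- base_coords(d)
  ix <- bc$x - offset_mm[1] / vol$spacing[1]
  iy <- bc$y - offset_mm[2] / vol$spacing[2]
  iz <- bc$z - offset_mm[3] / vol$spacing[3]
  # clamp to the grid so the vacated border repeats edge values
  ix <- pmin(pmax(ix, 1), d[1])
  iy <- pmin(pmax(iy, 1), d[2])
  iz <- pmin(pmax(iz, 1), d[3])
  xm <- vol$voxels; dim(xm) <- c(prod(d), 1L)
  out <- array(trilinear_gather(xm, d, ix, iy, iz)[, 1], d)
  volume(out, vol$spacing, modality = vol$modality, units = vol$units,
         origin = vol$origin, orientation = vol$orientation)
}

#' Clip a label's caudal extent relative to a PTV
#'
#' Removes label voxels on slices more than `caudal_margin_mm` caudal
#' to the most caudal PTV slice (the clinical convention of limiting
#' the structure to 1 cm beyond the planning target volume).
#'
#' @param label binary mask (`volume` or array).
#' @param ptv nonempty binary PTV mask on the same grid.
#' @param caudal_margin_mm margin in mm (default 10).
#' @param spacing voxel spacing for array inputs.
#' @param axis slice axis (default 3).
#' @param caudal `"low"` if caudal = decreasing slice index.
#' @return clipped mask, same type as `label`.
#' @export
clip_label_extent <- function(label, ptv, caudal_margin_mm = 10,
                              spacing = NULL, axis = 3L,
                              caudal = c("low", "high")) {
  caudal <- match.arg(caudal)
  lv <- as_array3d(label); pv <- as_array3d(ptv) > 0.5
  stopifnot_same_grid(lv, pv, "label and PTV")
  if (!any(pv)) stop("empty PTV: caudal limit undefined")
  if (is_volume(label)) spacing <- label$spacing
  if (is.null(spacing)) stop("spacing required for array labels")
  slices <- apply(pv, axis, any)
  n_beyond <- floor(caudal_margin_mm / spacing[axis])
  keep <- rep(FALSE, dim(lv)[axis])
  if (caudal == "low") {
    lim <- max(min(which(slices)) - n_beyond, 1L)
    keep[lim:length(keep)] <- TRUE
  } else {
    lim <- min(max(which(slices)) + n_beyond, length(keep))
    keep[1:lim] <- TRUE
  }
  out <- lv
  idx <- lapply(dim(lv), seq_len)
  idx[[axis]] <- which(!keep)
  if (length(idx[[axis]])) out[idx[[1]], idx[[2]], idx[[3]]] <- 0
  if (is_volume(label)) {
    binary_mask(out, label$spacing, origin = label$origin)
  } else out
}

#' Generate one synthetic phantom sample
#'
#' Deterministic given `spec$seed`.  Returns CT (HU, on the CT grid),
#' the MRI on its native grid (shifted by the misregistration vector),
#' the MRI resampled onto the CT grid, the clean vessel label, a noisy
#' label (clean label dilated by `label_noise_dilation_mm`, restricted
#' to muscle/bone/vessel tissue), the PTV, the tissue region maps and
#' the spec echo.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom_sample`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  run_with_seed(spec$seed, {
    d <- spec$grid
    geom <- phantom_geometry(spec)
    reg <- rasterise_regions(geom, d, spec$spacing)
    if (!any(reg$vessel)) stop("vessels not placeable on this grid")
    ct_clean <- array(spec$background_hu, d)
    ct_clean[reg$muscle] <- spec$muscle_hu
    ct_clean[reg$bone] <- spec$bone_hu
    ct_clean[reg$vessel] <- spec$vessel_ct_hu
    ct_vox <- ct_clean + stats::rnorm(length(ct_clean), sd = spec$noise_sigma[["ct"]])
    ct_vox <- pmin(pmax(ct_vox, -1024), 3072)
    ct <- volume(array(ct_vox, d), spec$spacing, "CT")

    # MRI on its native grid, geometry shifted by the misregistration
    dm <- as.integer(ceiling(d * spec$spacing / spec$mri_spacing))
    regm <- rasterise_regions(geom, dm, spec$mri_spacing,
                              shift_mm = spec$misregistration_mm)
    mri_vox <- array(spec$mri_background, dm)
    mri_vox[regm$muscle] <- spec$mri_muscle
    mri_vox[regm$bone] <- spec$mri_bone
    mri_vox[regm$vessel] <- spec$vessel_mri_intensity
    mri_vox <- mri_vox + stats::rnorm(length(mri_vox), sd = spec$noise_sigma[["mri"]])
    mri_native <- volume(pmin(pmax(mri_vox, 0), 1.2), spec$mri_spacing, "MRI")
    mri_ct <- resample_to_grid(mri_native, ct, interpolation = "linear")

    ptv <- ptv_mask(geom, d, spec$spacing)
    clean <- array(as.numeric(reg$vessel), d)
    clean <- clip_label_extent(clean, ptv, spec$caudal_margin_mm,
                               spacing = spec$spacing)
    if (spec$label_noise_dilation_mm > 0) {
      dil <- edt_sq(clean > 0.5, spec$spacing) <= spec$label_noise_dilation_mm^2
      tissue <- reg$muscle | reg$bone | reg$vessel
      shell <- dil & tissue & !(clean > 0.5)
      keep <- array(stats::runif(length(shell)) < spec$label_noise_keep, d)
      noisy <- array(as.numeric((clean > 0.5) | (shell & keep)), d)
    } else {
      noisy <- clean
    }
    structure(list(
      ct = ct,
      mri_native = mri_native,
      mri = mri_ct,
      label = binary_mask(clean, spec$spacing),
      label_noisy = binary_mask(noisy, spec$spacing),
      ptv = binary_mask(array(as.numeric(ptv), d), spec$spacing),
      regions = list(vessel = reg$vessel, muscle = reg$muscle, bone = reg$bone),
      regions_mri = list(vessel = regm$vessel, muscle = regm$muscle,
                         bone = regm$bone),
      misregistration_mm = spec$misregistration_mm,
      spec = spec
    ), class = "phantom_sample")
  })
}

#' Analytic dose field on a volume's grid
#'
#' `"uniform"`: constant dose.  `"gradient"`: linear fall-off along an
#' axis from `high_gy` to `low_gy`.  `"focal"`: dose decaying with
#' distance from a centre point.  Used as the planned-dose stand-in for
#' dosimetric evaluation.
#'
#' @param template volume defining the grid.
#' @param kind `"uniform"`, `"gradient"` or `"focal"`.
#' @param value uniform dose (Gy).
#' @param high_gy,low_gy gradient endpoints.
#' @param axis gradient axis.
#' @param centre_mm,d0_gy,falloff_mm focal parameters.
#' @return dose `volume` (Gy).
#' @export
analytic_dose <- function(template, kind = c("uniform", "gradient", "focal"),
                          value = 25, high_gy = 40, low_gy = 0, axis = 3L,
                          centre_mm = NULL, d0_gy = 40, falloff_mm = 15) {
  kind <- match.arg(kind)
  stopifnot(is_volume(template))
  d <- dim(template$voxels)
  if (kind == "uniform") {
    dv <- array(value, d)
  } else if (kind == "gradient") {
    t <- (seq_len(d[axis]) - 1) / max(1, d[axis] - 1)
    prof <- high_gy + (low_gy - high_gy) * t
    dv <- array(0, d)
    idx <- lapply(d, seq_len)
    for (k in seq_len(d[axis])) {
      idx[[axis]] <- k
      dv[idx[[1]], idx[[2]], idx[[3]]] <- prof[k]
    }
  } else {
    if (is.null(centre_mm)) centre_mm <- (d - 1) * template$spacing / 2
    co <- grid_coords_mm(d, template$spacing, c(0, 0, 0))
    r <- sqrt((co$x - centre_mm[1])^2 + (co$y - centre_mm[2])^2 +
                (co$z - centre_mm[3])^2)
    dv <- array(d0_gy * exp(-r / falloff_mm), d)
  }
  volume(dv, template$spacing, modality = "DOSE",
         origin = template$origin, orientation = template$orientation)
}

#' Generate a train/test phantom benchmark
#'
#' Draws per-sample parameters (seed, misregistration) from seeded
#' streams, generates `n_train + n_test` phantoms, and optionally
#' writes them to disk as NIfTI plus a JSON manifest with per-file
#' checksums.  Train and test samples come from disjoint seed streams.
#'
#' @param n_train,n_test sample counts (> 0).
#' @param spec base [phantom_spec()]; per-sample fields are jittered.
#' @param misreg_max_mm 3-vector of maximum |misregistration| per axis.
#' @param noise_dilation_range_mm per-sample label-noise dilation is
#'   drawn uniformly from this range (contour sloppiness varies from
#'   patient to patient); set both ends to 0 for clean labels.
#' @param seed master seed.
#' @param out_dir optional output directory.
#' @return list with `train`, `test` (lists of `phantom_sample`) and
#'   `manifest`; samples are also on disk when `out_dir` is given.
#' @export
make_benchmark <- function(n_train, n_test, spec = phantom_spec(),
                           misreg_max_mm = c(2, 2, 1),
                           noise_dilation_range_mm = c(1.5, 4), seed = 7L,
                           out_dir = NULL) {
  stopifnot(n_train > 0, n_test > 0)
  draw <- function(n, offset) {
    lapply(seq_len(n), function(i) {
      run_with_seed(seed + offset + i, {
        s <- spec
        s$seed <- sample.int(.Machine$integer.max %/% 2L, 1L)
        s$misregistration_mm <- stats::runif(3, -misreg_max_mm, misreg_max_mm)
        s$label_noise_dilation_mm <- stats::runif(1, noise_dilation_range_mm[1],
                                                  noise_dilation_range_mm[2])
        generate_phantom(s)
      })
    })
  }
  train <- draw(n_train, 0L)
  test <- draw(n_test, 100000L)
  manifest <- list(seed = seed, n_train = n_train, n_test = n_test,
                   grid = spec$grid, spacing = spec$spacing,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    write_sample <- function(s, name) {
      sd <- file.path(out_dir, name)
      dir.create(sd, showWarnings = FALSE)
      write_volume(s$ct, file.path(sd, "ct.nii.gz"))
      write_volume(s$mri_native, file.path(sd, "mri.nii.gz"))
      write_volume(s$label, file.path(sd, "label.nii.gz"))
      write_volume(s$label_noisy, file.path(sd, "label_noisy.nii.gz"))
      write_volume(s$ptv, file.path(sd, "ptv.nii.gz"))
      meta <- list(seed = s$spec$seed,
                   misregistration_mm = s$misregistration_mm,
                   grid = s$spec$grid, spacing = s$spec$spacing)
      jsonlite::write_json(meta, file.path(sd, "meta.json"),
                           auto_unbox = TRUE, digits = NA)
      files <<- c(files, list.files(sd, full.names = TRUE))
    }
    for (i in seq_along(train)) write_sample(train[[i]], sprintf("train_%03d", i))
    for (i in seq_along(test)) write_sample(test[[i]], sprintf("test_%03d", i))
    sums <- tools::md5sum(sort(files))
    manifest$files <- lapply(seq_along(sums), function(i)
      list(path = sub(paste0("^", out_dir, "/?"), "", names(sums)[i]),
           md5 = unname(sums[i])))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(train = train, test = test, manifest = manifest)
}
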