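## 3-D reconstruction and display transforms. CT colonography archives are
## anisotropic only along z (in-plane 0.55-0.98 mm vs 1-5 mm slice spacing),
## so resampling is per-column 1-D linear interpolation along z; the in-plane
## grid is untouched.

new_ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing %s mm | origin %s mm | HU range [%.4g, %.4g]\n",
              paste(format(x$spacing, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Assemble a sorted series into a 3-D HU volume
#'
#' Stacks the slices in ascending effective location (sorting first, so a
#' shuffled series yields the same volume), rescales stored values to
#' Hounsfield units, and infers the z spacing as the median inter-slice
#' difference. In-plane spacing comes from Pixel Spacing.
#'
#' @param series A `series_record` whose instances share matrix size and
#'   pixel spacing.
#' @param gap_factor Refuses to assemble when any inter-slice difference
#'   exceeds `gap_factor` times the inferred spacing (a missing slice; see
#'   [detect_missing_slices()]).
#' @return A `ct_volume`: `data` (rows x cols x slices array of HU),
#'   `spacing` (x, y, z in mm), `origin` (mm).
#' @export
assemble_volume <- function(series, gap_factor = 1.5) {
  if (length(series$instances) == 0) {
    abort("empty series", class = "ctcurate_geometry_error")
  }
  series <- sort_instances(series)
  insts <- series$instances
  dims <- vapply(insts, function(x) {
    c(dcm_num1(x, "Rows"), dcm_num1(x, "Columns"))
  }, numeric(2))
  if (anyNA(dims) || length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1) {
    abort("heterogeneous matrix size across slices", class = "ctcurate_geometry_error")
  }
  ps <- dcm_value(insts[[1]], "PixelSpacing")
  if (is.null(ps) || length(ps) < 2) ps <- c(1, 1)
  locs <- slice_locations(series)
  nz <- length(insts)
  if (nz > 1) {
    d <- diff(locs)
    zsp <- stats::median(d)
    if (zsp <= .loc_tol) {
      abort("degenerate slice spacing (duplicate locations)",
            class = "ctcurate_geometry_error")
    }
    gap <- detect_missing_slices(locs, factor = gap_factor)
    if (!gap$indeterminate && nrow(gap$gaps) > 0) {
      abort(sprintf("refusing to assemble: MISSING_SLICE gap between %.4g and %.4g mm",
                    gap$gaps$location_before[1], gap$gaps$location_after[1]),
            class = "ctcurate_missing_slice_error")
    }
  } else {
    zsp <- dcm_num1(insts[[1]], "SliceThickness")
    if (is.na(zsp) || zsp <= 0) zsp <- 1
  }
  nr <- as.integer(dims[1, 1]); nc <- as.integer(dims[2, 1])
  data <- array(0, dim = c(nr, nc, nz))
  for (k in seq_len(nz)) data[, , k] <- pixel_hu(insts[[k]])
  ipp <- dcm_value(insts[[1]], "ImagePositionPatient")
  origin <- if (!is.null(ipp) && length(ipp) == 3) as.numeric(ipp) else
    c(0, 0, locs[1])
  new_ct_volume(data, spacing = c(as.numeric(ps[1]), as.numeric(ps[2]), zsp),
                origin = origin)
}

#' Resample a volume along z by linear interpolation
#'
#' Interpolates each (x, y) column linearly along z at positions
#' `origin_z + k * target_z` within the original extent; grid endpoints are
#' reproduced exactly and no extrapolation occurs. Used to move an
#' anisotropic stack (e.g. 2.5 mm slices over ~0.7 mm pixels) toward
#' isotropic voxels; the default target is the in-plane pixel spacing.
#'
#' @param vol A `ct_volume` with at least two slices.
#' @param target_z New z spacing in mm (default `min(vol$spacing[1:2])`).
#' @return A resampled `ct_volume`.
#' @export
resample_z_linear <- function(vol, target_z = min(vol$spacing[1:2])) {
  stopifnot(inherits(vol, "ct_volume"))
  if (target_z <= 0) {
    abort("target_z must be positive", class = "ctcurate_geometry_error")
  }
  nz <- dim(vol$data)[3]
  if (nz < 2) {
    abort("cannot interpolate a single-slice volume",
          class = "ctcurate_geometry_error")
  }
  extent <- (nz - 1) * vol$spacing[3]
  new_z <- seq(0, extent + 1e-9, by = target_z)
  new_z <- new_z[new_z <= extent + 1e-9]
  pos <- new_z / vol$spacing[3]
  i0 <- pmin(floor(pos), nz - 2) + 1L   # lower bracketing slice (1-based)
  w <- pos - (i0 - 1L)
  w[w < 1e-12] <- 0                     # snap to grid: identity on grid points
  w[w > 1 - 1e-12] <- 1
  out <- array(0, dim = c(dim(vol$data)[1:2], length(new_z)))
  for (k in seq_along(new_z)) {
    if (w[k] == 0) {
      out[, , k] <- vol$data[, , i0[k]]
    } else if (w[k] == 1) {
      out[, , k] <- vol$data[, , i0[k] + 1L]
    } else {
      out[, , k] <- (1 - w[k]) * vol$data[, , i0[k]] + w[k] * vol$data[, , i0[k] + 1L]
    }
  }
  new_ct_volume(out, spacing = c(vol$spacing[1:2], target_z), origin = vol$origin)
}

#' Window/level and gamma display transform
#'
#' Maps HU values onto 8-bit display gray levels: the window of width `W`
#' centered at level `L` is normalized as
#' `clip((v - (L - W/2)) / W, 0, 1)`, gamma correction raises the normalized
#' value to `gamma`, and the result is scaled to `[0, 255]` with
#' round-half-up. The default `W = 400, L = 40` is the standard soft-tissue
#' abdomen window; `gamma = 1` leaves the normalized value unchanged.
#'
#' @param x Numeric vector/matrix/array of HU values, or a `ct_volume`.
#' @param width Window width `W` in HU (> 0).
#' @param level Window level (center) `L` in HU.
#' @param gamma Gamma exponent (> 0) applied to the window-normalized value.
#' @return Integer array of the same shape with values in 0..255.
#' @examples
#' apply_window(c(-160, 40, 240))  # lower clip, mid-gray, upper clip
#' @export
apply_window <- function(x, width = 400, level = 40, gamma = 1) {
  if (inherits(x, "ct_volume")) x <- x$data
  if (width <= 0) abort("window width must be positive", class = "ctcurate_config_error")
  if (gamma <= 0) abort("gamma must be positive", class = "ctcurate_config_error")
  v <- (x - (level - width / 2)) / width
  v <- pmin(pmax(v, 0), 1)
  if (gamma != 1) v <- v^gamma
  out <- as.integer(floor(v * 255 + 0.5))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Digitally reconstructed radiograph by mean projection
#'
#' Averages HU along one axis of the volume (an artificial X-ray) and maps
#' the result to 8-bit with [apply_window()].
#'
#' @param vol A `ct_volume`.
#' @param axis `"z"` (axial, default), `"y"`, or `"x"`.
#' @param width,level,gamma Display transform parameters.
#' @return Integer matrix in 0..255.
#' @export
drr_project <- function(vol, axis = c("z", "y", "x"), width = 400, level = 40,
                        gamma = 1) {
  stopifnot(inherits(vol, "ct_volume"))
  axis <- match.arg(axis)
  margin <- switch(axis, z = c(1, 2), y = c(1, 3), x = c(2, 3))
  proj <- apply(vol$data, margin, mean)
  apply_window(proj, width = width, level = level, gamma = gamma)
}

#' Export or import a volume as raw binary plus JSON sidecar
#'
#' The voxel data is written as little-endian float32 in x-fastest
#' (column-major) order; the sidecar records dimensions, spacing, origin and
#' dtype so the pair round-trips.
#'
#' @param vol A `ct_volume`.
#' @param prefix Output path prefix; writes `<prefix>.raw` and
#'   `<prefix>.json`.
#' @return `read_volume_raw()` returns the `ct_volume`.
#' @export
write_volume_raw <- function(vol, prefix) {
  stopifnot(inherits(vol, "ct_volume"))
  raw_path <- paste0(prefix, ".raw")
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  sidecar <- list(dim = dim(vol$data), spacing = vol$spacing,
                  origin = vol$origin, dtype = "float32",
                  byte_order = "little", order = "column-major")
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_volume_raw
#' @export
read_volume_raw <- function(prefix) {
  sidecar <- jsonlite::fromJSON(paste0(prefix, ".json"))
  d <- as.integer(sidecar$dim)
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(d), size = 4L, endian = "little")
  new_ct_volume(array(v, dim = d), spacing = as.numeric(sidecar$spacing),
                origin = as.numeric(sidecar$origin))
}

#' Export a volume as a single-file NIfTI image
#'
#' Convenience bridge to downstream neuroimaging viewers; requires the
#' RNifti package.
#'
#' @param vol A `ct_volume`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @export
write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("the RNifti package is required for NIfTI export",
          class = "ctcurate_config_error")
  }
  img <- RNifti::asNifti(vol$data, pixdim = vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export an 8-bit image as PNG
#'
#' @param img Integer matrix in 0..255 (e.g. from [apply_window()] or
#'   [drr_project()]).
#' @param path Output PNG path.
#' @export
write_image_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the png package is required for PNG export",
          class = "ctcurate_config_error")
  }
  png::writePNG(img / 255, path)
  invisible(path)
}
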