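#' Multi-channel 3D volume with voxel calibration
#'
#' A `volume_image` is the substrate of all image quantification: a 4-D
#' intensity array indexed `(channel, z, y, x)` together with the physical
#' voxel size in micrometres per axis and channel labels.
#'
#' @param data numeric 4-D array, dimensions `(channel, z, y, x)`, all
#'   intensities `>= 0`. A 3-D array is promoted to a single channel.
#' @param voxel_size numeric length-3, micrometres per voxel along
#'   `(z, y, x)`; all entries must be positive.
#' @param channel_names character vector of channel labels, one per channel.
#'
#' @return An object of class `volume_image` with elements `data`,
#'   `voxel_size` (named `dz`, `dy`, `dx`) and `channel_names`.
#' @examples
#' v <- volume_image(array(0, c(2, 4, 8, 8)), c(1, 0.5, 0.5), c("iba1", "cd68"))
#' dim(v$data)
#' @export
volume_image <- function(data, voxel_size, channel_names = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  if (length(dim(data)) != 4L)
    stop("'data' must be a (channel, z, y, x) array")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive values (dz, dy, dx) in um")
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  nc <- dim(data)[1L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("'channel_names' length must equal the channel count")
  structure(
    list(data = data,
         voxel_size = stats::setNames(as.numeric(voxel_size),
                                      c("dz", "dy", "dx")),
         channel_names = as.character(channel_names)),
    class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d channel(s) [%s], %d x %d x %d voxels (z,y,x)\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  voxel size (um): dz=%g dy=%g dx=%g\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Binary voxel mask
#'
#' @param data logical 3-D array `(z, y, x)`.
#' @param voxel_size micrometres per voxel `(dz, dy, dx)`.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(data, voxel_size) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D (z, y, x) array")
  if (!is.logical(data)) storage.mode(data) <- "logical"
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive values (dz, dy, dx)")
  structure(
    list(data = data,
         voxel_size = stats::setNames(as.numeric(voxel_size),
                                      c("dz", "dy", "dx"))),
    class = "binary_mask")
}

# channel label or index -> index, with validation
resolve_channel <- function(volume, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > dim(volume$data)[1L])
      stop(sprintf("channel index %d out of range", ch))
    return(ch)
  }
  ch <- match(channel, volume$channel_names)
  if (is.na(ch))
    stop(sprintf("unknown channel '%s' (have: %s)", channel,
                 paste(volume$channel_names, collapse = ", ")))
  ch
}

#' Region-of-interest specification in physical units
#'
#' ROIs are rectangular fields of view given in micrometres on the `(y, x)`
#' plane, matching per-lamina reporting (e.g. a 245 um x 65 um field per
#' lamina band). Conversion to voxels uses 0-based half-open intervals: the
#' origin is floored and the far edge is ceiled, so the crop always covers
#' the requested physical extent.
#'
#' @param name label, e.g. `"LI-II"` or `"LIII-IV"`.
#' @param origin_um numeric `(y, x)` offset of the ROI corner in um.
#' @param extent_um numeric `(height, width)` in um; must be positive.
#' @param z_range integer `(z0, z1)` 1-based inclusive slice interval, or
#'   `NULL` for the full stack.
#' @return A `roi_spec` object.
#' @export
roi_spec <- function(name, origin_um, extent_um, z_range = NULL) {
  if (length(origin_um) != 2L || length(extent_um) != 2L)
    stop("'origin_um' and 'extent_um' must each have length 2 (y, x)")
  if (any(extent_um <= 0)) stop("ROI extent must be positive")
  if (any(origin_um < 0)) stop("ROI origin must be >= 0")
  structure(list(name = as.character(name),
                 origin_um = as.numeric(origin_um),
                 extent_um = as.numeric(extent_um),
                 z_range = if (is.null(z_range)) NULL else as.integer(z_range)),
            class = "roi_spec")
}

# um -> half-open voxel interval [i0, i1) (0-based), floor origin, ceil edge
roi_voxel_interval <- function(origin_um, extent_um, step_um, n_vox) {
  i0 <- floor(origin_um / step_um)
  i1 <- ceiling((origin_um + extent_um) / step_um)
  if (i0 < 0 || i1 > n_vox)
    stop(sprintf("ROI [%g, %g] um exceeds volume extent %g um",
                 origin_um, origin_um + extent_um, n_vox * step_um))
  c(i0, i1)
}

#' Crop a volume to a region of interest
#'
#' @param volume a [volume_image].
#' @param roi a [roi_spec]; micrometre coordinates are converted to voxels
#'   with 0-based half-open indexing (origin floored, far edge ceiled).
#' @return The cropped [volume_image]; channels and voxel size preserved.
#' @examples
#' v <- volume_image(array(1, c(1, 4, 490, 130)), c(2, 0.5, 0.5))
#' cr <- crop_roi(v, roi_spec("LI-II", c(0, 0), c(245, 65)))
#' dim(cr$data)   # 1 4 490 130
#' @export
crop_roi <- function(volume, roi) {
  stopifnot(inherits(volume, "volume_image"), inherits(roi, "roi_spec"))
  d <- dim(volume$data)
  iy <- roi_voxel_interval(roi$origin_um[1], roi$extent_um[1],
                           volume$voxel_size["dy"], d[3])
  ix <- roi_voxel_interval(roi$origin_um[2], roi$extent_um[2],
                           volume$voxel_size["dx"], d[4])
  zr <- if (is.null(roi$z_range)) c(1L, d[2]) else roi$z_range
  if (zr[1] < 1L || zr[2] > d[2] || zr[1] > zr[2])
    stop("ROI z_range outside the stack")
  volume_image(
    volume$data[, zr[1]:zr[2], (iy[1] + 1L):iy[2], (ix[1] + 1L):ix[2],
                drop = FALSE],
    volume$voxel_size, volume$channel_names)
}
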