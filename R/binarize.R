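#' Otsu threshold of an intensity sample
#'
#' Exhaustive maximisation of the between-class variance over 256 histogram
#' cut points spanning the intensity range. The returned value is the lower
#' edge of the first bin assigned to foreground; voxels with intensity
#' strictly greater than the threshold are foreground.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins number of histogram bins (default 256, 8-bit convention).
#' @return The scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("constant-intensity volume: Otsu is undefined; use a fixed threshold")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  # between-class variance at each cut (foreground = bins above the cut)
  sb <- rep(-Inf, n_bins)
  sb[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sb)
  edges[k + 1L]
}

#' Binarize one channel of a volume
#'
#' The per-channel threshold is either computed by Otsu's method on the
#' channel's intensity histogram or supplied as a fixed value. Voxels with
#' intensity strictly above the threshold become foreground. The chosen
#' method and value are attached to the mask for provenance.
#'
#' @param volume a [volume_image].
#' @param channel channel label or index.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value threshold intensity, required iff `method = "fixed"`.
#' @return A [binary_mask] with attributes `threshold_method` and
#'   `threshold_value`.
#' @examples
#' v <- volume_image(array(c(0, 100), c(1, 2, 4, 4)), c(1, 1, 1))
#' m <- binarize_channel(v, 1, method = "fixed", fixed_value = 50)
#' sum(m$data)
#' @export
binarize_channel <- function(volume, channel, method = c("otsu", "fixed"),
                             fixed_value = NULL) {
  stopifnot(inherits(volume, "volume_image"))
  method <- match.arg(method)
  ch <- resolve_channel(volume, channel)
  arr <- volume$data[ch, , , , drop = TRUE]
  dim(arr) <- dim(volume$data)[2:4]
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("method='fixed' requires 'fixed_value'")
    thr <- as.numeric(fixed_value)
    if (length(thr) != 1L || !is.finite(thr))
      stop("'fixed_value' must be a single finite intensity")
  } else {
    if (!is.null(fixed_value)) stop("'fixed_value' only applies to method='fixed'")
    thr <- otsu_threshold(arr)
  }
  m <- binary_mask(arr > thr, volume$voxel_size)
  attr(m, "threshold_method") <- method
  attr(m, "threshold_value") <- thr
  m
}

#' Voxelwise intersection of binary masks
#'
#' @param masks list of two or more [binary_mask] objects with identical
#'   shapes and voxel sizes.
#' @return A [binary_mask]: the logical AND of all inputs.
#' @export
intersect_masks <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L)
    stop("'masks' must be a list of >= 2 binary masks")
  stopifnot(all(vapply(masks, inherits, TRUE, "binary_mask")))
  d0 <- dim(masks[[1L]]$data)
  v0 <- masks[[1L]]$voxel_size
  for (m in masks[-1L]) {
    if (!identical(dim(m$data), d0)) stop("mask shape mismatch")
    if (!isTRUE(all.equal(unname(m$voxel_size), unname(v0))))
      stop("mask voxel-size mismatch")
  }
  out <- masks[[1L]]$data
  for (m in masks[-1L]) out <- out & m$data
  binary_mask(out, v0)
}

#' Physical volume of a mask
#'
#' @param mask a [binary_mask].
#' @return Foreground voxel count times the voxel volume, in cubic
#'   micrometres.
#' @examples
#' m <- binary_mask(array(TRUE, c(2, 3, 4)), c(0.5, 0.1, 0.1))
#' mask_volume(m)  # 24 * 0.005
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * prod(mask$voxel_size)
}
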