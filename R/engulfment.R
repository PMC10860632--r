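#' Quantify microglial engulfment in one field of view
#'
#' Reproduces the triple-colocalization readout of phagocytosed fiber
#' material: each channel is binarized, and three nested volumes are
#' measured inside the ROI: the microglial (Iba1) volume, the microglial
#' lysosome volume (CD68 within Iba1), and the engulfed fiber volume (fiber
#' signal within CD68 within Iba1). The nesting
#' `engulfed <= lysosome <= microglia` holds by construction because each
#' quantity is an intersection volume of a superset of the previous masks.
#'
#' @param volume a [volume_image] with microglia, lysosome and fiber
#'   channels.
#' @param microglia_ch,lysosome_ch,fiber_ch channel labels or indices.
#' @param roi optional [roi_spec]; when given, quantification is restricted
#'   to the cropped field of view.
#' @param thresholds either the string `"otsu"` (default; per-channel Otsu)
#'   or a named numeric vector of fixed thresholds keyed by the channel
#'   labels used above.
#' @return A one-row data.frame of class `engulfment_result` with columns
#'   `roi`, `microglia_um3`, `lysosome_um3`, `engulfed_um3`,
#'   `threshold_method` and per-channel `threshold_*` values.
#' @export
quantify_engulfment <- function(volume, microglia_ch = "microglia",
                                lysosome_ch = "lysosome", fiber_ch = "fiber",
                                roi = NULL, thresholds = "otsu") {
  stopifnot(inherits(volume, "volume_image"))
  if (!is.null(roi)) volume <- crop_roi(volume, roi)
  chans <- c(microglia = microglia_ch, lysosome = lysosome_ch,
             fiber = fiber_ch)
  masks <- lapply(chans, function(ch) {
    if (identical(thresholds, "otsu")) {
      binarize_channel(volume, ch, method = "otsu")
    } else {
      key <- if (is.character(ch)) ch else volume$channel_names[ch]
      if (is.null(names(thresholds)) || !key %in% names(thresholds))
        stop(sprintf("no fixed threshold supplied for channel '%s'", key))
      binarize_channel(volume, ch, method = "fixed",
                       fixed_value = thresholds[[key]])
    }
  })
  lyso <- intersect_masks(masks[c("lysosome", "microglia")])
  engf <- intersect_masks(list(masks$fiber, lyso))
  out <- data.frame(
    roi = if (is.null(roi)) "full" else roi$name,
    microglia_um3 = mask_volume(masks$microglia),
    lysosome_um3 = mask_volume(lyso),
    engulfed_um3 = mask_volume(engf),
    threshold_method = if (identical(thresholds, "otsu")) "otsu" else "fixed",
    threshold_microglia = attr(masks$microglia, "threshold_value"),
    threshold_lysosome = attr(masks$lysosome, "threshold_value"),
    threshold_fiber = attr(masks$fiber, "threshold_value"),
    stringsAsFactors = FALSE)
  class(out) <- c("engulfment_result", class(out))
  out
}

#' Count and measure synaptic puncta
#'
#' The synaptic-stain channel is binarized, 3-D connected components are
#' labeled with 26-connectivity, components below a minimum voxel size are
#' discarded, and the object count and summed physical volume are returned.
#'
#' @param volume a [volume_image].
#' @param channel channel label or index of the synaptic stain.
#' @param roi optional [roi_spec].
#' @param threshold `"otsu"` (default) or a fixed numeric threshold.
#' @param min_voxels discard components with fewer foreground voxels than
#'   this (default 0: no size filter).
#' @return A one-row data.frame of class `puncta_result` with columns `roi`,
#'   `count`, `total_um3`, `min_voxels`, `threshold_method`,
#'   `threshold_value`.
#' @export
quantify_puncta <- function(volume, channel = 1L, roi = NULL,
                            threshold = "otsu", min_voxels = 0L) {
  stopifnot(inherits(volume, "volume_image"))
  if (!is.null(roi)) volume <- crop_roi(volume, roi)
  mask <- if (identical(threshold, "otsu")) {
    binarize_channel(volume, channel, method = "otsu")
  } else {
    binarize_channel(volume, channel, method = "fixed",
                     fixed_value = threshold)
  }
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L], attr(lab, "n_components"))
  keep <- sizes >= min_voxels
  out <- data.frame(
    roi = if (is.null(roi)) "full" else roi$name,
    count = sum(keep),
    total_um3 = sum(sizes[keep]) * prod(mask$voxel_size),
    min_voxels = as.integer(min_voxels),
    threshold_method = attr(mask, "threshold_method"),
    threshold_value = attr(mask, "threshold_value"),
    stringsAsFactors = FALSE)
  class(out) <- c("puncta_result", class(out))
  out
}

#' Batch quantification across sections and ROIs
#'
#' Runs [quantify_engulfment()] (and optionally [quantify_puncta()]) on
#' every volume x ROI combination and aggregates per-animal means for the
#' statistics stage. A QC warning is emitted for any animal contributing
#' fewer than `min_sections` sections, following the reporting rule that at
#' least six sections be analyzed per animal.
#'
#' @param volumes list of [volume_image] objects.
#' @param metadata data.frame with one row per volume: columns `animal` and
#'   `section` are required.
#' @param rois list of [roi_spec] (or `NULL` for a single full-volume ROI).
#' @param channels named list/vector with entries `microglia`, `lysosome`,
#'   `fiber` and optionally `puncta`.
#' @param thresholds passed through to the quantifiers.
#' @param min_voxels puncta size filter.
#' @param min_sections QC minimum sections per animal (default 6).
#' @return A list with elements `sections` (one row per section x ROI),
#'   `animals` (per-animal, per-ROI means) and `warnings` (character vector
#'   of QC messages, also raised via [warning()]).
#' @export
batch_quantify <- function(volumes, metadata, rois = NULL,
                           channels = c(microglia = "microglia",
                                        lysosome = "lysosome",
                                        fiber = "fiber"),
                           thresholds = "otsu", min_voxels = 0L,
                           min_sections = 6L) {
  if (length(volumes) != nrow(metadata))
    stop("'metadata' must have one row per volume")
  req <- c("animal", "section")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata missing required fields: ", paste(miss, collapse = ", "))
  if (is.null(rois)) rois <- list(NULL)
  rows <- list()
  for (i in seq_along(volumes)) {
    for (roi in rois) {
      er <- quantify_engulfment(volumes[[i]],
                                microglia_ch = channels[["microglia"]],
                                lysosome_ch = channels[["lysosome"]],
                                fiber_ch = channels[["fiber"]],
                                roi = roi, thresholds = thresholds)
      row <- cbind(data.frame(animal = metadata$animal[i],
                              section = metadata$section[i],
                              stringsAsFactors = FALSE), er)
      if ("puncta" %in% names(channels)) {
        pr <- quantify_puncta(volumes[[i]], channel = channels[["puncta"]],
                              roi = roi, threshold = thresholds[1],
                              min_voxels = min_voxels)
        row$puncta_count <- pr$count
        row$puncta_um3 <- pr$total_um3
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  sections <- do.call(rbind, rows)
  n_sec <- tapply(sections$section, sections$animal,
                  function(s) length(unique(s)))
  warns <- character(0)
  low <- names(n_sec)[n_sec < min_sections]
  if (length(low)) {
    warns <- sprintf("QC: animal '%s' has only %d section(s) (< %d required)",
                     low, n_sec[low], min_sections)
    for (w in warns) warning(w, call. = FALSE)
  }
  num_cols <- intersect(c("microglia_um3", "lysosome_um3", "engulfed_um3",
                          "puncta_count", "puncta_um3"), names(sections))
  animals <- stats::aggregate(sections[num_cols],
                              by = list(animal = sections$animal,
                                        roi = sections$roi), FUN = mean)
  list(sections = sections, animals = animals, warnings = warns)
}
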