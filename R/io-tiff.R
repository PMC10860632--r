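# Minimal baseline TIFF I/O: little-endian, uncompressed, single-sample
# grayscale pages. The pre-installed R stack has no TIFF package, so this
# reads and writes the subset of baseline TIFF the pipeline needs
# (float32 phantoms; 8/16-bit unsigned and float32 on read). Multi-channel
# z-stacks are stored channel-major: pages 1..nz are channel 1, and so on.
# Voxel calibration and channel names live in a JSON sidecar.

tiff_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)

write_ifd_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == tiff_types["SHORT"] && count == 1L) {
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a volume as a multi-page TIFF with JSON sidecar
#'
#' Pages are channel-major (all z of channel 1, then channel 2, ...),
#' uncompressed 32-bit float, little-endian. The sidecar
#' `<path>.json` records voxel size (um), channel names, stack shape and
#' any extra metadata (e.g. phantom ground truth), and is required to read
#' the volume back.
#'
#' @param volume a [volume_image].
#' @param path output TIFF path.
#' @param metadata optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, metadata = NULL) {
  stopifnot(inherits(volume, "volume_image"))
  d <- dim(volume$data)                      # (c, z, y, x)
  nc <- d[1]; nz <- d[2]; ny <- d[3]; nx <- d[4]
  n_pages <- nc * nz
  page_bytes <- nx * ny * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  # layout: header(8) | pixel data (n_pages * page_bytes) | IFD chain
  data_start <- 8L
  ifd_start <- data_start + n_pages * page_bytes
  ifd_size <- 2L + 10L * 12L + 4L
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
    sl <- volume$data[ci, zi, , ]
    dim(sl) <- c(ny, nx)
    writeBin(as.numeric(t(sl)), con, size = 4, endian = "little")
  }
  for (p in seq_len(n_pages)) {
    writeBin(10L, con, size = 2, endian = "little")        # entry count
    write_ifd_entry(con, 256, 4, 1, nx)                    # ImageWidth
    write_ifd_entry(con, 257, 4, 1, ny)                    # ImageLength
    write_ifd_entry(con, 258, 3, 1, 32)                    # BitsPerSample
    write_ifd_entry(con, 259, 3, 1, 1)                     # Compression
    write_ifd_entry(con, 262, 3, 1, 1)                     # Photometric
    write_ifd_entry(con, 273, 4, 1, data_start + (p - 1L) * page_bytes)
    write_ifd_entry(con, 277, 3, 1, 1)                     # SamplesPerPixel
    write_ifd_entry(con, 278, 4, 1, ny)                    # RowsPerStrip
    write_ifd_entry(con, 279, 4, 1, page_bytes)            # StripByteCounts
    write_ifd_entry(con, 339, 3, 1, 3)                     # SampleFormat
    nxt <- if (p < n_pages) ifd_start + p * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  side <- c(list(voxel_size_um = unname(volume$voxel_size),
                 channel_names = volume$channel_names,
                 n_channels = nc, n_z = nz, n_y = ny, n_x = nx),
            metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

read_u <- function(raw, off, size) {
  # unsigned little-endian integer from raw at 0-based offset
  sum(as.integer(raw[(off + 1L):(off + size)]) * 256^(0:(size - 1L)))
}

parse_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (rawToChar(raw[1:2]) != "II")
    stop("only little-endian TIFF is supported")
  if (read_u(raw, 2, 2) != 42L) stop("not a TIFF file")
  type_size <- c(1L, 1L, 2L, 4L, 8L)         # BYTE ASCII SHORT LONG RATIONAL
  read_values <- function(off, type, count) {
    sz <- type_size[type]
    inline <- sz * count <= 4L
    base <- if (inline) off + 8L else read_u(raw, off + 8L, 4L)
    vapply(seq_len(count) - 1L, function(i) read_u(raw, base + i * sz, sz), 0)
  }
  pages <- list()
  ifd <- read_u(raw, 4, 4)
  while (ifd != 0L) {
    n <- read_u(raw, ifd, 2)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- read_u(raw, off, 2)
      type <- read_u(raw, off + 2L, 2)
      count <- read_u(raw, off + 4L, 4)
      if (type %in% c(1, 3, 4))
        tags[[as.character(tag)]] <- read_values(off, type, count)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (!identical(g(259, 1), 1)) stop("compressed TIFF is not supported")
    w <- g(256); h <- g(257)
    bits <- g(258, 1)[1]
    fmt <- g(339, 1)[1]
    offs <- g(273); cnts <- g(279)
    if (is.null(w) || is.null(h) || is.null(offs))
      stop("malformed TIFF page: missing geometry or strip offsets")
    buf <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1L):(offs[i] + cnts[i])]))
    px <- if (fmt == 3 && bits == 32) {
      readBin(buf, "double", n = w * h, size = 4, endian = "little")
    } else if (bits == 8) {
      as.numeric(readBin(buf, "integer", n = w * h, size = 1, signed = FALSE,
                         endian = "little"))
    } else if (bits == 16) {
      as.numeric(readBin(buf, "integer", n = w * h, size = 2, signed = FALSE,
                         endian = "little"))
    } else stop(sprintf("unsupported pixel format: %d-bit sampleformat %d",
                        bits, fmt))
    pages[[length(pages) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
    ifd <- read_u(raw, ifd + 2L + n * 12L, 4)
  }
  pages
}

#' Read a volume written with [write_volume()]
#'
#' Requires the JSON sidecar: a volume without voxel-size metadata is
#' meaningless and raises a hard error naming the missing field.
#'
#' @param path TIFF path; the sidecar is looked up at `<path>.json`.
#' @param channel_map optional character vector renaming/reordering
#'   channels: entries must exist in the sidecar's `channel_names`.
#' @return A [volume_image]; sidecar metadata beyond the geometry is
#'   attached as attribute `metadata`.
#' @export
read_volume <- function(path, channel_map = NULL) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing sidecar '%s': field 'voxel_size_um' unavailable", sc))
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(side$voxel_size_um))
    stop("sidecar missing required field 'voxel_size_um'")
  pages <- parse_tiff_pages(path)
  nc <- if (is.null(side$n_channels)) 1L else as.integer(side$n_channels)
  nz <- length(pages) / nc
  if (nz != round(nz))
    stop("page count is not a multiple of the sidecar channel count")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(nc, nz, ny, nx))
  for (ci in seq_len(nc)) for (zi in seq_len(nz))
    arr[ci, zi, , ] <- pages[[(ci - 1L) * nz + zi]]
  chn <- if (is.null(side$channel_names)) NULL else side$channel_names
  v <- volume_image(arr, side$voxel_size_um, chn)
  if (!is.null(channel_map)) {
    idx <- vapply(channel_map, resolve_channel, 0L, volume = v)
    v <- volume_image(v$data[idx, , , , drop = FALSE], v$voxel_size,
                      names(channel_map) %||% channel_map)
  }
  extra <- side[setdiff(names(side), c("voxel_size_um", "channel_names",
                                       "n_channels", "n_z", "n_y", "n_x"))]
  attr(v, "metadata") <- extra
  v
}

`%||%` <- function(x, y) if (is.null(x)) y else x
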