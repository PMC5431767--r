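# Minimal multi-page 16-bit grayscale TIFF I/O.
#
# No TIFF package is assumed: this is a self-contained baseline codec writing
# little-endian, uncompressed, single-strip, 16-bit unsigned grayscale pages
# (the reconstruction format used for the scans this pipeline targets), plus a
# YAML sidecar carrying voxel size and axis order. The reader accepts exactly
# this baseline subset and refuses anything else.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Write a volume as 16-bit multi-page TIFF with a YAML sidecar
#'
#' Grey values are rounded and clamped to the 16-bit range `[0, 65535]` at
#' write time only (analysis always runs on unclamped doubles). The sidecar
#' `<path>.yaml` records `voxel_size_um`, `axis_order` and `origin_um`, so a
#' round trip restores the full [grey_volume()].
#'
#' @param vol a [grey_volume()].
#' @param path output TIFF file path.
#' @param sidecar write the YAML sidecar next to the TIFF? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar = TRUE) {
  stopifnot(inherits(vol, "grey_volume"))
  d <- dim(vol$values)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  v <- round(vol$values)
  v[v < 0] <- 0
  v[v > 65535] <- 65535
  v <- as.integer(v)

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")

  writeBin(charToRaw("II"), con)  # little-endian
  w16(42L)
  page_bytes <- nx * ny * 2L
  ifd_bytes <- 2L + 10L * 12L + 4L
  # layout per page: [pixel data][IFD]; first IFD offset points past the header
  first_data <- 8L
  data_off <- function(p) first_data + (p - 1L) * (page_bytes + ifd_bytes)
  ifd_off <- function(p) data_off(p) + page_bytes
  w32(ifd_off(1L))

  entry <- function(tag, type, value) { w16(tag); w16(type); w32(1L); w32(value) }
  for (p in seq_len(nz)) {
    page <- v[seq.int(p, length(v), by = nz)]         # [y, x] slice, column-major
    page <- matrix(page, nrow = ny, ncol = nx)
    pix <- as.integer(t(page))                        # row-major scanlines
    pix[pix > 32767L] <- pix[pix > 32767L] - 65536L   # two's complement for writeBin
    writeBin(pix, con, size = 2L, endian = "little")
    w16(10L)  # entry count
    entry(TIFF_TAGS[["ImageWidth"]], 4L, nx)
    entry(TIFF_TAGS[["ImageLength"]], 4L, ny)
    entry(TIFF_TAGS[["BitsPerSample"]], 3L, 16L)
    entry(TIFF_TAGS[["Compression"]], 3L, 1L)
    entry(TIFF_TAGS[["Photometric"]], 3L, 1L)         # BlackIsZero
    entry(TIFF_TAGS[["StripOffsets"]], 4L, data_off(p))
    entry(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L)
    entry(TIFF_TAGS[["RowsPerStrip"]], 4L, ny)
    entry(TIFF_TAGS[["StripByteCounts"]], 4L, page_bytes)
    entry(TIFF_TAGS[["SampleFormat"]], 3L, 1L)        # unsigned integer
    w32(if (p < nz) ifd_off(p + 1L) else 0L)
  }

  if (sidecar) {
    yaml::write_yaml(
      list(voxel_size_um = vol$voxel_size, axis_order = "z,y,x",
           origin_um = vol$origin, shape = as.integer(d)),
      sidecar_path(path)
    )
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Read a volume written by [write_volume()]
#'
#' Supports the baseline subset this package writes: little-endian,
#' uncompressed, 16-bit unsigned grayscale, one strip per page. Voxel size and
#' origin are taken from the YAML sidecar when present (defaults: 7 um, origin
#' 0).
#'
#' @param path TIFF file path.
#' @return a [grey_volume()].
#' @export
read_volume <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  u32 <- function(off) {
    as.numeric(raw[off + 1L]) + 256 * as.numeric(raw[off + 2L]) +
      65536 * as.numeric(raw[off + 3L]) + 16777216 * as.numeric(raw[off + 4L])
  }
  if (rawToChar(raw[1:2]) != "II" || u16(2L) != 42L) {
    stop("unsupported TIFF: expected little-endian baseline TIFF", call. = FALSE)
  }
  ifd <- u32(4L)
  pages <- list()
  while (ifd != 0) {
    n_entries <- u16(ifd)
    tags <- list()
    for (e in seq_len(n_entries)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- u16(off)
      type <- u16(off + 2L)
      val <- if (type == 3L) u16(off + 8L) else u32(off + 8L)
      tags[[as.character(tag)]] <- val
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(v)) {
        if (is.null(default)) stopf("unsupported TIFF: missing %s tag", tag) else default
      } else v
    }
    if (need("Compression", 1L) != 1L) stop("unsupported TIFF: compressed data", call. = FALSE)
    if (need("BitsPerSample", 1L) != 16L) stop("unsupported TIFF: not 16-bit", call. = FALSE)
    if (need("SamplesPerPixel", 1L) != 1L) stop("unsupported TIFF: not single-channel", call. = FALSE)
    nx <- need("ImageWidth"); ny <- need("ImageLength")
    so <- need("StripOffsets"); sb <- need("StripByteCounts")
    if (sb != nx * ny * 2) stop("unsupported TIFF: multiple strips per page", call. = FALSE)
    bytes <- raw[(so + 1):(so + sb)]
    vals <- readBin(bytes, "integer", n = nx * ny, size = 2L,
                    signed = FALSE, endian = "little")
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = nx, ncol = ny))  # [y, x]
    ifd <- u32(ifd + 2L + n_entries * 12L)
  }
  nz <- length(pages)
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (p in seq_len(nz)) arr[p, , ] <- pages[[p]]

  voxel <- 7; origin <- c(0, 0, 0)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    if (!is.null(meta$voxel_size_um)) voxel <- as.numeric(meta$voxel_size_um)
    if (!is.null(meta$origin_um)) origin <- as.numeric(meta$origin_um)
    if (!is.null(meta$axis_order) && !identical(meta$axis_order, "z,y,x")) {
      stop("unsupported axis order in sidecar (expected z,y,x)", call. = FALSE)
    }
  }
  grey_volume(arr, voxel_size = voxel, origin = origin)
}
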