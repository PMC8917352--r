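## Minimal baseline TIFF codec (uncompressed, single-sample grayscale,
## multi-page).  The installed R stack ships no TIFF reader, and microscope
## time-lapse stacks are the package's native input, so the subset of the
## format the pipeline needs is implemented here: little/big-endian files,
## 8/16-bit unsigned integer and 32-bit float samples, one sample per pixel,
## any strip layout, no compression.  Anything else is rejected with a
## descriptive error rather than mis-read.

TIFF_TYPE_SIZES <- c(BYTE = 1L, ASCII = 1L, SHORT = 2L, LONG = 4L,
                     RATIONAL = 8L)

#' Write a grayscale multi-page TIFF
#'
#' Writes an uncompressed baseline TIFF with one image per page. Intended
#' for FRAP stacks and masks produced by this package; `dtype` controls the
#' on-disk sample format.
#'
#' @param frames A numeric matrix (single page) or 3D array indexed
#'   `[frame, y, x]`.
#' @param path Output file path.
#' @param dtype One of `"uint8"`, `"uint16"`, `"float32"`. Integer dtypes
#'   require values within the representable range; values are rounded.
#' @return `path`, invisibly.
#' @seealso [read_tiff_stack()]
#' @export
write_tiff_stack <- function(frames, path, dtype = c("float32", "uint16",
                                                     "uint8")) {
  dtype <- match.arg(dtype)
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1L, nrow(frames), ncol(frames)))
  }
  stopifnot(length(dim(frames)) == 3L)
  n <- dim(frames)[1]
  h <- dim(frames)[2]
  w <- dim(frames)[3]
  bps <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- switch(dtype, uint8 = 1L, uint16 = 1L, float32 = 3L)
  bytes_per_px <- bps / 8L
  strip_bytes <- h * w * bytes_per_px

  if (dtype != "float32") {
    vmax <- 2^bps - 1
    rng <- range(frames)
    if (rng[1] < 0 || rng[2] > vmax) {
      stop(sprintf("values outside [0, %d] cannot be written as %s",
                   vmax, dtype))
    }
  }

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                              endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                              endian = "little")

  ## header: II, magic 42, offset of first IFD
  writeBin(charToRaw("II"), con)
  w16(42L)
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  ## layout: header (8) | page strips | IFD chain
  data_start <- 8L
  strip_offsets <- data_start + (seq_len(n) - 1L) * strip_bytes
  ifd_start <- data_start + n * strip_bytes
  ifd_offsets <- ifd_start + (seq_len(n) - 1L) * ifd_size
  w32(ifd_offsets[1])

  for (i in seq_len(n)) {
    ## TIFF stores rows sequentially: transpose [y, x] to row-major order
    v <- as.vector(t(frames[i, , ]))
    if (dtype == "float32") {
      writeBin(as.double(v), con, size = 4L, endian = "little")
    } else {
      writeBin(as.integer(round(v)), con, size = bytes_per_px,
               endian = "little")
    }
  }

  tag <- function(id, type, count, value) {
    w16(id); w16(type); w32(count)
    if (type == 3L) {             # SHORT: left-justified in the value slot
      w16(value); w16(0L)
    } else {
      w32(value)
    }
  }
  for (i in seq_len(n)) {
    w16(n_tags)
    tag(256L, 4L, 1L, w)                 # ImageWidth
    tag(257L, 4L, 1L, h)                 # ImageLength
    tag(258L, 3L, 1L, bps)               # BitsPerSample
    tag(259L, 3L, 1L, 1L)                # Compression = none
    tag(262L, 3L, 1L, 1L)                # Photometric = BlackIsZero
    tag(273L, 4L, 1L, strip_offsets[i])  # StripOffsets
    tag(277L, 3L, 1L, 1L)                # SamplesPerPixel
    tag(278L, 4L, 1L, h)                 # RowsPerStrip
    tag(279L, 4L, 1L, strip_bytes)       # StripByteCounts
    tag(339L, 3L, 1L, fmt)               # SampleFormat
    w32(if (i < n) ifd_offsets[i + 1] else 0L)
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Supports uncompressed baseline TIFF, single sample per pixel, 8/16-bit
#' unsigned integer or 32-bit float samples, either byte order. RGB or
#' multi-sample files are rejected ("grayscale required"), as is any
#' compression.
#'
#' @param path TIFF file path.
#' @return 3D numeric array indexed `[frame, y, x]`.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  rd <- function(offset, what, n, size, signed = TRUE) {
    readBin(raw[(offset + 1):(offset + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  u16 <- function(off, n = 1L) rd(off, "integer", n, 2L, signed = FALSE)
  u32 <- function(off, n = 1L) rd(off, "integer", n, 4L)
  if (u16(2L) != 42L) stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  ifd_off <- u32(4L)
  while (ifd_off != 0L) {
    n_tags <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      id <- u16(e)
      type <- u16(e + 2L)
      count <- u32(e + 4L)
      size <- switch(as.character(type), `1` = 1L, `3` = 2L, `4` = 4L, NA)
      if (is.na(size)) { tags[[as.character(id)]] <- NULL; next }
      total <- size * count
      voff <- if (total <= 4L) e + 8L else u32(e + 8L)
      vals <- switch(as.character(type),
                     `1` = as.integer(raw[(voff + 1):(voff + count)]),
                     `3` = u16(voff, count),
                     `4` = u32(voff, count))
      tags[[as.character(id)]] <- vals
    }
    gt <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- gt(256); h <- gt(257)
    if (is.null(w) || is.null(h)) stop("malformed TIFF: missing dimensions")
    if (gt(277, 1L) != 1L || length(gt(258, 8L)) != 1L) {
      stop("grayscale required: multi-sample (e.g. RGB) TIFF not supported")
    }
    if (gt(259, 1L) != 1L) stop("compressed TIFF not supported")
    bps <- gt(258, 8L)
    fmt <- gt(339, 1L)
    offs <- gt(273); cnts <- gt(279)
    if (is.null(offs) || is.null(cnts)) stop("malformed TIFF: missing strips")
    bytes <- unlist(mapply(function(o, cn) raw[(o + 1):(o + cn)],
                           offs, cnts, SIMPLIFY = FALSE))
    npx <- as.integer(w) * as.integer(h)
    v <- if (fmt == 3L && bps == 32L) {
      readBin(bytes, "double", n = npx, size = 4L, endian = endian)
    } else if (fmt %in% c(1L, 2L) && bps == 8L) {
      as.numeric(as.integer(bytes))
    } else if (fmt %in% c(1L, 2L) && bps == 16L) {
      as.numeric(readBin(bytes, "integer", n = npx, size = 2L,
                         signed = (fmt == 2L), endian = endian))
    } else {
      stop(sprintf("unsupported TIFF sample layout: %d-bit, format %d",
                   bps, fmt))
    }
    pages[[length(pages) + 1L]] <- t(matrix(v, nrow = w, ncol = h))
    ifd_off <- u32(ifd_off + 2L + n_tags * 12L)
  }
  if (!length(pages)) stop("TIFF contains no images: ", path)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  out <- array(0, dim = c(length(pages), h, w))
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), c(h, w))) {
      stop("TIFF pages have inconsistent dimensions")
    }
    out[i, , ] <- pages[[i]]
  }
  out
}
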