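# Minimal baseline TIFF codec: uncompressed, single-sample grayscale,
# 16-bit unsigned (raw/simulated counts) or 32-bit float (parametric maps).
# Written because no TIFF-capable R package is available in the target
# environment; round-trips are asserted in the test suite, including against
# an external reader. Writer emits little-endian, single-strip files; the
# reader additionally accepts big-endian and multi-strip layouts.


#' Write a grayscale image as baseline TIFF
#'
#' @param image numeric matrix (row-major display orientation: rows are image
#'   rows).
#' @param path output path.
#' @param type `"uint16"` (values must be integers in `[0, 65535]`) or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path, type = c("uint16", "float32")) {
  type <- match.arg(type)
  stopifnot(is.matrix(image), is.numeric(image))
  ny <- nrow(image); nx <- ncol(image)
  if (type == "uint16") {
    if (any(!is.finite(image)) || any(image < 0 | image > 65535) ||
        any(image != round(image)))
      stop("uint16 TIFF requires integer values in [0, 65535]")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  bps <- if (type == "uint16") 16L else 32L
  sfmt <- if (type == "uint16") 1L else 3L
  nbytes <- ny * nx * (bps / 8L)
  data_off <- 8L
  ifd_off <- data_off + nbytes
  # header
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  # pixel data, row-major
  px <- as.vector(t(image))
  if (type == "uint16") {
    # writeBin has no unsigned 16-bit: map to signed range
    v <- as.integer(px)
    v[v > 32767L] <- v[v > 32767L] - 65536L
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(px), con, size = 4, endian = "little")
  }
  # IFD
  tags <- list(
    c(256L, 4L, 1L, nx),          # ImageWidth
    c(257L, 4L, 1L, ny),          # ImageLength
    c(258L, 3L, 1L, bps),         # BitsPerSample
    c(259L, 3L, 1L, 1L),          # Compression = none
    c(262L, 3L, 1L, 1L),          # Photometric = BlackIsZero
    c(273L, 4L, 1L, data_off),    # StripOffsets
    c(277L, 3L, 1L, 1L),          # SamplesPerPixel
    c(278L, 4L, 1L, ny),          # RowsPerStrip
    c(279L, 4L, 1L, nbytes),      # StripByteCounts
    c(339L, 3L, 1L, sfmt)         # SampleFormat
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    if (tg[2] == 3L) { # SHORT value, left-justified in 4-byte slot
      writeBin(as.integer(tg[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}

.read_uint <- function(raw, off, size, endian) {
  idx <- seq.int(off + 1L, off + size)
  b <- as.integer(raw[idx])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_along(b) - 1))
}

#' Read a baseline grayscale TIFF
#'
#' Supports what [write_tiff()] emits plus big-endian and multi-strip
#' uncompressed single-sample files (16-bit unsigned or 32-bit float).
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file: ", path)
  if (.read_uint(raw, 2L, 2L, endian) != 42) stop("bad TIFF magic in ", path)
  ifd <- .read_uint(raw, 4L, 4L, endian)
  n_tags <- .read_uint(raw, ifd, 2L, endian)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd + 2L + (i - 1L) * 12L
    id <- .read_uint(raw, base, 2L, endian)
    typ <- .read_uint(raw, base + 2L, 2L, endian)
    cnt <- .read_uint(raw, base + 4L, 4L, endian)
    tsz <- c(1L, 1L, 2L, 4L, 8L)[typ]
    if (is.na(tsz)) tsz <- 4L
    vals <- if (cnt * tsz <= 4L) {
      vapply(seq_len(cnt), function(k)
        .read_uint(raw, base + 8L + (k - 1L) * tsz, tsz, endian), numeric(1))
    } else {
      voff <- .read_uint(raw, base + 8L, 4L, endian)
      vapply(seq_len(cnt), function(k)
        .read_uint(raw, voff + (k - 1L) * tsz, tsz, endian), numeric(1))
    }
    tags[[as.character(id)]] <- vals
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", id, " missing in ", path)
      default
    } else v
  }
  nx <- need(256); ny <- need(257); bps <- need(258)
  if (need(259, 1) != 1) stop("compressed TIFF not supported")
  if (need(277, 1) != 1) stop("only single-sample grayscale supported")
  sfmt <- need(339, 1)
  offs <- need(273); counts <- need(279, ny * nx * bps / 8)
  buf <- raw(0)
  for (k in seq_along(offs))
    buf <- c(buf, raw[(offs[k] + 1L):(offs[k] + counts[k])])
  npx <- nx * ny
  px <- if (bps == 16 && sfmt == 1) {
    readBin(buf, "integer", n = npx, size = 2, signed = FALSE,
            endian = endian)
  } else if (bps == 32 && sfmt == 3) {
    readBin(buf, "numeric", n = npx, size = 4, endian = endian)
  } else stop(sprintf("unsupported TIFF layout (%d bps, format %d)", bps,
                      sfmt))
  matrix(px, nrow = ny, ncol = nx, byrow = TRUE)
}

#' Write / read an angle manifest for an image stack
#'
#' Sidecar tab-delimited text carrying, per image: file name, analyzer
#' offset (microradians) and the normalization (expected object-free counts
#' at that offset). Kept out of TIFF tags for dialect safety.
#'
#' @param files image file names (relative to the manifest directory).
#' @param thetas analyzer offsets, microradians.
#' @param norms normalization counts.
#' @param path manifest path.
#' @return `read_manifest` returns a data.frame with columns `file`,
#'   `theta`, `norm`.
#' @export
write_manifest <- function(files, thetas, norms, path) {
  stopifnot(length(files) == length(thetas), length(thetas) == length(norms))
  d <- data.frame(file = files, theta = thetas, norm = norms)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric", "numeric"))
}
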