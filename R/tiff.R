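# Minimal baseline-TIFF I/O. The offline toolchain has no TIFF/PNG package,
# so the package carries its own reader/writer restricted to the subset it
# emits: uncompressed, chunky planar layout, 8-bit unsigned or 32-bit float
# samples, 1-6 samples per pixel. The reader additionally accepts multi-strip
# files and both byte orders.

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L,
                 SBYTE = 6L, UNDEF = 7L, SSHORT = 8L, SLONG = 9L,
                 SRATIONAL = 10L, FLOAT = 11L, DOUBLE = 12L)
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' Write an image array as an uncompressed TIFF
#'
#' @param img Numeric array `H x W x C` (or `H x W` matrix) with `C` in 1..6.
#' @param path Output file path.
#' @param format `"uint8"` (values 0-255, rounded) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, format = c("uint8", "float32")) {
  format <- match.arg(format)
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  stopifnot(length(dim(img)) == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]; spp <- dim(img)[3]
  if (spp < 1 || spp > 6) stop("1 to 6 samples per pixel supported")
  bps <- if (format == "uint8") 8L else 32L
  sfmt <- if (format == "uint8") 1L else 3L
  bytes_per_sample <- bps %/% 8L
  nbytes <- h * w * spp * bytes_per_sample
  data_off <- 8L
  ifd_off <- data_off + nbytes
  if (ifd_off %% 2L == 1L) ifd_off <- ifd_off + 1L

  inline_arrays <- spp <= 2L
  n_entries <- 11L
  extra_off <- ifd_off + 2L + n_entries * 12L + 4L
  # trailing arrays for BitsPerSample / SampleFormat when they do not fit
  bits_off <- extra_off
  sfmt_off <- extra_off + 2L * spp

  entry <- function(tag, type, count, value) {
    # value left-justified in the 4-byte field (little-endian file)
    c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
      writeBin(as.integer(type), raw(), size = 2, endian = "little"),
      writeBin(as.integer(count), raw(), size = 4, endian = "little"),
      value)
  }
  long4 <- function(v) writeBin(as.integer(v), raw(), size = 4,
                                endian = "little")
  shorts <- function(v) {
    out <- unlist(lapply(as.integer(v), function(x)
      writeBin(x, raw(), size = 2, endian = "little")))
    if (length(out) < 4) out <- c(out, raw(4 - length(out)))
    out
  }

  bits_val <- if (inline_arrays) shorts(rep(bps, spp)) else long4(bits_off)
  sfmt_val <- if (inline_arrays) shorts(rep(sfmt, spp)) else long4(sfmt_off)
  entries <- c(
    entry(256, .tiff_types["LONG"], 1, long4(w)),
    entry(257, .tiff_types["LONG"], 1, long4(h)),
    entry(258, .tiff_types["SHORT"], spp, bits_val),
    entry(259, .tiff_types["SHORT"], 1, shorts(1L)),          # no compression
    entry(262, .tiff_types["SHORT"], 1,
          shorts(if (spp == 3L) 2L else 1L)),                  # RGB / gray
    entry(273, .tiff_types["LONG"], 1, long4(data_off)),       # strip offset
    entry(277, .tiff_types["SHORT"], 1, shorts(spp)),
    entry(278, .tiff_types["LONG"], 1, long4(h)),              # rows per strip
    entry(279, .tiff_types["LONG"], 1, long4(nbytes)),
    entry(284, .tiff_types["SHORT"], 1, shorts(1L)),           # chunky
    entry(339, .tiff_types["SHORT"], spp, sfmt_val))

  # pixel-interleaved, row-major: channel fastest, then column, then row
  vals <- as.vector(aperm(img, c(3L, 2L, 1L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  if (format == "uint8") {
    v <- pmin(pmax(round(vals), 0), 255)
    writeBin(as.raw(v), con)
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  if ((data_off + nbytes) %% 2L == 1L) writeBin(raw(1), con)
  writeBin(as.integer(n_entries), con, size = 2, endian = "little")
  writeBin(entries, con)
  writeBin(0L, con, size = 4, endian = "little")
  if (!inline_arrays) {
    writeBin(as.integer(rep(bps, spp)), con, size = 2, endian = "little")
    writeBin(as.integer(rep(sfmt, spp)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed TIFF into an array
#'
#' Supports the subset written by [write_tiff()] plus multi-strip layouts and
#' big-endian files: 8-bit unsigned or 32-bit float samples, chunky planar
#' configuration, no compression.
#'
#' @param path TIFF file path.
#' @return Numeric array `H x W x C`; uint8 data is returned on the 0-255
#'   scale, float data as stored. Attribute `sample_format` is `"uint8"` or
#'   `"float32"`.
#' @export
read_tiff <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  rd <- function(off, what, n, size, endian, signed = TRUE)
    readBin(bytes[(off + 1):length(bytes)], what, n = n, size = size,
            endian = endian, signed = signed)
  magic <- rawToChar(bytes[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file: ", path)
  if (rd(2, "integer", 1, 2, endian) != 42L) stop("bad TIFF magic: ", path)
  ifd <- rd(4, "integer", 1, 4, endian)
  n_ent <- rd(ifd, "integer", 1, 2, endian)
  tags <- list()
  for (i in seq_len(n_ent)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- rd(off, "integer", 1, 2, endian, signed = FALSE)
    type <- rd(off + 2, "integer", 1, 2, endian)
    count <- rd(off + 4, "integer", 1, 4, endian)
    size <- .tiff_type_size[type] * count
    voff <- if (size <= 4) off + 8 else rd(off + 8, "integer", 1, 4, endian)
    val <- switch(as.character(type),
      "1" = rd(voff, "integer", count, 1, endian, signed = FALSE),
      "3" = rd(voff, "integer", count, 2, endian, signed = FALSE),
      "4" = rd(voff, "integer", count, 4, endian),
      NULL)
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bps <- unique(need(258, 1L)); spp <- need(277, 1L)
  comp <- need(259, 1L); planar <- need(284, 1L)
  sfmt <- unique(need(339, 1L))
  if (comp != 1L) stop("compressed TIFF not supported: ", path)
  if (planar != 1L) stop("planar TIFF not supported: ", path)
  if (length(bps) != 1L) stop("mixed bit depths not supported: ", path)
  offsets <- need(273); counts <- need(279)
  raw_data <- unlist(lapply(seq_along(offsets), function(i)
    bytes[(offsets[i] + 1):(offsets[i] + counts[i])]), use.names = FALSE)
  n_samples <- h * w * spp
  if (bps == 8L && sfmt %in% c(1L, 4L)) {
    vals <- as.integer(raw_data[seq_len(n_samples)])
    fmt <- "uint8"
  } else if (bps == 32L && sfmt == 3L) {
    vals <- readBin(raw_data, "numeric", n = n_samples, size = 4,
                    endian = endian)
    fmt <- "float32"
  } else stop("unsupported TIFF sample layout (", bps, "-bit, format ",
              sfmt, "): ", path)
  img <- aperm(array(vals, c(spp, w, h)), c(3L, 2L, 1L))
  attr(img, "sample_format") <- fmt
  img
}
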