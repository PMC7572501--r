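# Minimal baseline TIFF codec for uncompressed unsigned grayscale images.
#
# Profile: uint8/uint16, 1 sample/pixel, no compression, strip-organized,
# both byte orders on read, little-endian ("II") on write. This is the
# de facto interchange profile for light-sheet microscopy slice stacks.
# Anything outside the profile (RGB, floating point, compressed, tiled)
# is rejected with a message naming the offending page rather than being
# converted silently.

TIFF_TAG <- list(width = 256L, length = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, strip_offsets = 273L, spp = 277L,
                 rows_per_strip = 278L, strip_bytes = 279L,
                 sample_format = 339L, tile_width = 322L)

ru16 <- function(raw, pos, le) {
  b <- as.integer(raw[pos + 0:1])
  if (le) b[1L] + 256L * b[2L] else b[2L] + 256L * b[1L]
}

ru32 <- function(raw, pos, le) {
  b <- as.numeric(as.integer(raw[pos + 0:3]))
  if (!le) b <- rev(b)
  b[1L] + 256 * b[2L] + 65536 * b[3L] + 16777216 * b[4L]
}

# Read one IFD entry's value vector (SHORT=3 or LONG=4 only).
tiff_entry_values <- function(raw, entry_pos, le) {
  type <- ru16(raw, entry_pos + 2L, le)
  count <- ru32(raw, entry_pos + 4L, le)
  size <- switch(as.character(type), "3" = 2L, "4" = 4L, NULL)
  if (is.null(size)) return(NULL)  # types we never need (RATIONAL etc.)
  total <- size * count
  pos <- if (total <= 4L) entry_pos + 8L else ru32(raw, entry_pos + 8L, le) + 1L
  rdr <- if (size == 2L) ru16 else ru32
  vapply(seq_len(count) - 1L, function(i) rdr(raw, pos + i * size, le),
         numeric(1L))
}

#' Read all pages of a grayscale TIFF file
#'
#' @param path file path.
#' @return list with `planes` (list of integer matrices, `(y, x)`) and
#'   `bit_depth`.
#' @keywords internal
read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop(sprintf("'%s' is not a TIFF file", path))
  order_tag <- rawToChar(raw[1:2])
  le <- order_tag == "II"
  if (!le && order_tag != "MM")
    stop(sprintf("'%s' is not a TIFF file (bad byte-order mark)", path))
  if (ru16(raw, 3L, le) != 42L)
    stop(sprintf("'%s' is not a TIFF file (bad magic)", path))
  ifd <- ru32(raw, 5L, le)
  planes <- list()
  bit_depth <- NULL
  page <- 0L
  while (ifd != 0) {
    page <- page + 1L
    pos <- ifd + 1L  # 1-based
    n_entries <- ru16(raw, pos, le)
    tags <- list()
    for (k in seq_len(n_entries)) {
      ep <- pos + 2L + (k - 1L) * 12L
      tag <- ru16(raw, ep, le)
      tags[[as.character(tag)]] <- tiff_entry_values(raw, ep, le)
    }
    gv <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    who <- sprintf("page %d of '%s'", page, path)
    if (!is.null(gv(TIFF_TAG$tile_width)))
      stop(sprintf("%s: tiled TIFF not supported", who))
    comp <- gv(TIFF_TAG$compression, 1)
    if (comp != 1) stop(sprintf("%s: compressed TIFF not supported", who))
    spp <- gv(TIFF_TAG$spp, 1)
    if (spp != 1)
      stop(sprintf("%s: non-grayscale (samples per pixel = %d)", who, spp))
    sf <- gv(TIFF_TAG$sample_format, 1)
    if (sf == 3) stop(sprintf("%s: floating-point pages are rejected", who))
    if (sf != 1) stop(sprintf("%s: unsupported sample format %d", who, sf))
    bits <- gv(TIFF_TAG$bits, 1)[1L]
    if (!bits %in% c(8, 16))
      stop(sprintf("%s: unsupported bit depth %d", who, bits))
    w <- gv(TIFF_TAG$width); h <- gv(TIFF_TAG$length)
    if (is.null(w) || is.null(h)) stop(sprintf("%s: missing dimensions", who))
    offs <- gv(TIFF_TAG$strip_offsets)
    cnts <- gv(TIFF_TAG$strip_bytes)
    if (is.null(offs) || is.null(cnts))
      stop(sprintf("%s: missing strip layout", who))
    data <- raw(0)
    for (s in seq_along(offs))
      data <- c(data, raw[offs[s] + seq_len(cnts[s])])
    npx <- w * h
    if (bits == 8) {
      v <- as.integer(data[seq_len(npx)])
    } else {
      b <- as.integer(data[seq_len(2 * npx)])
      i1 <- seq(1L, 2L * npx, by = 2L)
      v <- if (le) b[i1] + 256L * b[i1 + 1L] else b[i1 + 1L] + 256L * b[i1]
    }
    # TIFF stores rows (y) consecutively, x fastest
    planes[[page]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    if (is.null(bit_depth)) bit_depth <- as.integer(bits)
    else if (bit_depth != bits)
      stop(sprintf("%s: bit depth %d differs from first page (%d)",
                   who, bits, bit_depth))
    ifd <- ru32(raw, pos + 2L + n_entries * 12L, le)
  }
  if (page == 0L) stop(sprintf("'%s' contains no pages", path))
  list(planes = planes, bit_depth = bit_depth)
}

wu16 <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

wu32 <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
               (v %/% 16777216) %% 256))
}

# RGB companion writer (8-bit, interleaved), used by the colormap stage's
# file output. Write-only: the pipeline never reads RGB back.
write_tiff_rgb <- function(path, rgb_planes) {
  n <- length(rgb_planes)
  ifd_size <- 2L + 10L * 12L + 4L
  data_len <- vapply(rgb_planes, length, numeric(1L))
  bits_off <- numeric(n); data_off <- numeric(n); ifd_off <- numeric(n)
  cursor <- 8
  for (i in seq_len(n)) {
    bits_off[i] <- cursor                  # 6 bytes: BitsPerSample 8,8,8
    data_off[i] <- cursor + 6
    ifd_off[i] <- data_off[i] + data_len[i]
    cursor <- ifd_off[i] + ifd_size
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), wu16(42L), wu32(ifd_off[1L])), con)
  for (i in seq_len(n)) {
    p <- rgb_planes[[i]]
    stopifnot(length(dim(p)) == 3L, dim(p)[3L] == 3L)
    h <- dim(p)[1L]; w <- dim(p)[2L]
    # interleave channels, x fastest within a row
    v <- aperm(p, c(3L, 2L, 1L))
    writeBin(c(wu16(8L), wu16(8L), wu16(8L), as.raw(as.integer(round(v)))),
             con)
    entries <- c(
      tiff_ifd_entry(TIFF_TAG$width, 4L, 1L, w),
      tiff_ifd_entry(TIFF_TAG$length, 4L, 1L, h),
      tiff_ifd_entry(TIFF_TAG$bits, 3L, 3L, wu32(bits_off[i])),
      tiff_ifd_entry(TIFF_TAG$compression, 3L, 1L, 1L),
      tiff_ifd_entry(TIFF_TAG$photometric, 3L, 1L, 2L),  # RGB
      tiff_ifd_entry(TIFF_TAG$strip_offsets, 4L, 1L, data_off[i]),
      tiff_ifd_entry(TIFF_TAG$spp, 3L, 1L, 3L),
      tiff_ifd_entry(TIFF_TAG$rows_per_strip, 4L, 1L, h),
      tiff_ifd_entry(TIFF_TAG$strip_bytes, 4L, 1L, data_len[i]),
      tiff_ifd_entry(TIFF_TAG$sample_format, 3L, 1L, 1L))
    next_ifd <- if (i < n) ifd_off[i + 1L] else 0
    writeBin(c(wu16(10L), entries, wu32(next_ifd)), con)
  }
  invisible(path)
}

tiff_ifd_entry <- function(tag, type, count, value) {
  # value already raw (4 bytes) or numeric scalar
  if (!is.raw(value)) {
    value <- if (type == 3L) c(wu16(value), as.raw(c(0L, 0L))) else wu32(value)
  }
  c(wu16(tag), wu16(type), wu32(count), value)
}

#' Write matrices as an uncompressed little-endian grayscale TIFF
#'
#' @param path destination file.
#' @param planes list of integer matrices `(y, x)`, one per page.
#' @param bit_depth 8 or 16.
#' @keywords internal
write_tiff_pages <- function(path, planes, bit_depth) {
  stopifnot(bit_depth %in% c(8L, 16L))
  bpp <- bit_depth / 8L
  n <- length(planes)
  ifd_size <- 2L + 10L * 12L + 4L
  # layout: header | page1 data | page1 IFD | page2 data | ...
  data_len <- vapply(planes, function(p) length(p) * bpp, numeric(1L))
  data_off <- numeric(n); ifd_off <- numeric(n)
  cursor <- 8
  for (i in seq_len(n)) {
    data_off[i] <- cursor
    ifd_off[i] <- cursor + data_len[i]
    cursor <- ifd_off[i] + ifd_size
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), wu16(42L), wu32(ifd_off[1L])), con)
  for (i in seq_len(n)) {
    p <- planes[[i]]
    v <- as.integer(round(t(p)))  # row-major: x fastest within a row
    writeBin(if (bit_depth == 8L) as.raw(v) else wu16(v), con)
    h <- nrow(p); w <- ncol(p)
    entries <- c(
      tiff_ifd_entry(TIFF_TAG$width, 4L, 1L, w),
      tiff_ifd_entry(TIFF_TAG$length, 4L, 1L, h),
      tiff_ifd_entry(TIFF_TAG$bits, 3L, 1L, bit_depth),
      tiff_ifd_entry(TIFF_TAG$compression, 3L, 1L, 1L),
      tiff_ifd_entry(TIFF_TAG$photometric, 3L, 1L, 1L),  # BlackIsZero
      tiff_ifd_entry(TIFF_TAG$strip_offsets, 4L, 1L, data_off[i]),
      tiff_ifd_entry(TIFF_TAG$spp, 3L, 1L, 1L),
      tiff_ifd_entry(TIFF_TAG$rows_per_strip, 4L, 1L, h),
      tiff_ifd_entry(TIFF_TAG$strip_bytes, 4L, 1L, data_len[i]),
      tiff_ifd_entry(TIFF_TAG$sample_format, 3L, 1L, 1L))
    next_ifd <- if (i < n) ifd_off[i + 1L] else 0
    writeBin(c(wu16(10L), entries, wu32(next_ifd)), con)
  }
  invisible(path)
}
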