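## Minimal baseline TIFF codec (uncompressed, 8-bit, chunky planar layout,
## grayscale or RGB, strip-organised, either byte order). No R TIFF reader
## is available in the supported environment, and the pipeline only needs
## baseline rasters, so the subset is implemented here.

.u16 <- function(raw, off, le) {
  b <- as.integer(raw[off + 1:2])
  if (le) b[1] + 256 * b[2] else b[2] + 256 * b[1]
}

.u32 <- function(raw, off, le) {
  b <- as.numeric(raw[off + 1:4])
  if (!le) b <- rev(b)
  b[1] + 256 * (b[2] + 256 * (b[3] + 256 * b[4]))
}

## Read the value vector of one IFD entry (types BYTE/SHORT/LONG).
.tiffEntryValues <- function(raw, entryOff, le) {
  type <- .u16(raw, entryOff + 2, le)
  count <- .u32(raw, entryOff + 4, le)
  size <- c(1, 1, 2, 4)[type]
  if (is.na(size)) return(NULL)
  total <- size * count
  valOff <- if (total <= 4) entryOff + 8 else .u32(raw, entryOff + 8, le)
  if (valOff + total > length(raw)) stop("truncated TIFF value", call. = FALSE)
  vapply(seq_len(count) - 1, function(i) {
    switch(as.character(size),
      "1" = as.numeric(raw[valOff + i + 1]),
      "2" = .u16(raw, valOff + 2 * i, le),
      "4" = .u32(raw, valOff + 4 * i, le))
  }, numeric(1))
}

.readTIFF <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("truncated TIFF: ", path, call. = FALSE)
  order <- rawToChar(raw[1:2])
  le <- order == "II"
  if (!le && order != "MM") stop("not a TIFF file: ", path, call. = FALSE)
  if (.u16(raw, 2, le) != 42) stop("not a TIFF file: ", path, call. = FALSE)
  ifd <- .u32(raw, 4, le)
  if (ifd + 2 > length(raw)) stop("truncated TIFF: ", path, call. = FALSE)
  nEntries <- .u16(raw, ifd, le)
  tags <- list()
  for (k in seq_len(nEntries)) {
    off <- ifd + 2 + 12 * (k - 1)
    if (off + 12 > length(raw)) stop("truncated TIFF: ", path, call. = FALSE)
    tag <- .u16(raw, off, le)
    tags[[as.character(tag)]] <- .tiffEntryValues(raw, off, le)
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing", call. = FALSE)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bps <- need(258, 8); spp <- need(277, 1)
  if (any(bps != 8)) stop("only 8-bit TIFF supported", call. = FALSE)
  if (need(259, 1) != 1) stop("only uncompressed TIFF supported", call. = FALSE)
  photometric <- need(262)
  if (!photometric %in% 0:2)
    stop("only grayscale/RGB TIFF supported", call. = FALSE)
  if (need(284, 1) != 1) stop("only chunky TIFF supported", call. = FALSE)
  offsets <- need(273); counts <- need(279)
  if (h < 1 || w < 1) stop("zero-sized TIFF raster", call. = FALSE)
  bytes <- raw(0)
  for (i in seq_along(offsets)) {
    if (offsets[i] + counts[i] > length(raw))
      stop("truncated TIFF strip data", call. = FALSE)
    bytes <- c(bytes, raw[offsets[i] + seq_len(counts[i])])
  }
  if (length(bytes) < h * w * spp)
    stop("truncated TIFF strip data", call. = FALSE)
  vals <- as.numeric(bytes[seq_len(h * w * spp)])
  ## chunky layout: sample fastest, then column, then row
  arr <- aperm(array(vals, c(spp, w, h)), c(3, 2, 1))
  if (photometric == 0) arr <- 255 - arr
  if (spp == 1L) arr <- array(arr, c(h, w, 3))
  else if (spp >= 3L) arr <- arr[, , 1:3, drop = FALSE]
  arr
}

.wu16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
.wu32 <- function(x)
  as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256,
           x %/% 16777216 %% 256))

.writeTIFF <- function(pixels, path) {
  d <- dim(pixels)
  h <- d[1]; w <- d[2]
  vals <- pmin(pmax(round(pixels), 0), 255)
  bytes <- as.raw(as.vector(aperm(vals, c(3, 2, 1))))
  len <- length(bytes)
  pad <- len %% 2L
  bpsOff <- 8 + len + pad
  ifdOff <- bpsOff + 6
  entry <- function(tag, type, count, value)
    c(.wu16(tag), .wu16(type), .wu32(count), .wu32(value))
  SHORT <- 3; LONG <- 4
  entries <- c(
    entry(256, LONG, 1, w), entry(257, LONG, 1, h),
    entry(258, SHORT, 3, bpsOff),      # three 8s stored before the IFD
    entry(259, SHORT, 1, 1),           # no compression
    entry(262, SHORT, 1, 2),           # RGB
    entry(273, LONG, 1, 8),            # single strip right after header
    entry(277, SHORT, 1, 3),
    entry(278, LONG, 1, h),
    entry(279, LONG, 1, len))
  out <- c(charToRaw("II"), .wu16(42), .wu32(ifdOff),
           bytes, raw(pad),
           .wu16(8), .wu16(8), .wu16(8),
           .wu16(9L), entries, .wu32(0))
  writeBin(out, path)
  invisible(path)
}
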