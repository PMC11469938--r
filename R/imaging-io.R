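## Section ingestion, pre-scoring geometry (downscale + tiling) and tissue
## masking. Fixed pipeline constants: sections are 50% downscaled and split
## into 512 x 512 tiles before per-tile grading.

#' Construct a SectionImage from a pixel array
#'
#' Grayscale matrices are replicated to three channels; values must already
#' be on the 8-bit [0, 255] scale.
#'
#' @param pixels numeric \code{h x w x 3} array or \code{h x w} matrix.
#' @param mpp microns per pixel, or \code{NA} when unknown.
#' @param stain one of [stainLabels()].
#' @param ident sample identifier.
#' @return A [SectionImage-class].
#' @export
#' @examples
#' s <- sectionImage(array(255, c(8, 8, 3)))
#' dim(sectionPixels(s))
sectionImage <- function(pixels, mpp = NA_real_, stain = "synthetic",
                         ident = "section") {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 3L))
  stain <- match.arg(stain, stainLabels())
  new("SectionImage", pixels = pixels, mpp = as.numeric(mpp), stain = stain,
      ident = ident)
}

#' Load a section raster from disk
#'
#' Reads a PNG or baseline (uncompressed, 8-bit) TIFF raster into a
#' [SectionImage-class]. The format is detected from the file's magic
#' bytes, not its extension. Grayscale inputs are replicated to three
#' channels; alpha channels are dropped.
#'
#' @param path file to read.
#' @param stain stain label, one of [stainLabels()].
#' @param mpp optional microns-per-pixel metadata (> 0).
#' @param ident sample identifier; defaults to the file name without
#'   extension.
#' @return A [SectionImage-class].
#' @export
loadSection <- function(path, stain = "synthetic", mpp = NA_real_,
                        ident = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  if (is.null(ident)) ident <- sub("\\.[A-Za-z]+$", "", basename(path))
  magic <- readBin(path, "raw", n = 4)
  pixels <- if (length(magic) >= 4 &&
                identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    a <- tryCatch(png::readPNG(path),
                  error = function(e) stop("failed to read PNG '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
    a <- round(a * 255)
    if (is.matrix(a)) array(a, c(dim(a), 3L))
    else if (dim(a)[3] == 2L) array(a[, , 1], c(dim(a)[1:2], 3L))
    else a[, , 1:3, drop = FALSE]
  } else if (length(magic) >= 2 &&
             rawToChar(magic[1:2]) %in% c("II", "MM")) {
    .readTIFF(path)
  } else {
    stop("'", path, "' is neither PNG nor TIFF", call. = FALSE)
  }
  sectionImage(pixels, mpp = mpp, stain = stain, ident = ident)
}

#' Write a section raster to disk
#'
#' @param section a [SectionImage-class].
#' @param path output file; format from extension (\code{.png} or
#'   \code{.tif}/\code{.tiff}).
#' @return \code{path}, invisibly.
#' @export
writeSection <- function(section, path) {
  px <- pmin(pmax(round(section@pixels), 0), 255)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(px / 255, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    .writeTIFF(px, path)
  } else stop("unsupported output format for '", path, "'", call. = FALSE)
  invisible(path)
}

## Row weights for 1-D area-average (box) resampling, nOut x nIn.
## Each output pixel averages the input interval it covers, with exact
## fractional overlap at the boundaries; rows are normalised so constant
## inputs are preserved.
.boxWeights <- function(nIn, nOut) {
  scale <- nIn / nOut
  W <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    a <- (i - 1) * scale
    b <- i * scale
    j0 <- floor(a) + 1L
    j1 <- min(ceiling(b), nIn)
    for (j in j0:j1) W[i, j] <- max(0, min(b, j) - max(a, j - 1))
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

## Area-average resize of an h x w x 3 array to hOut x wOut.
.resizeArea <- function(pixels, hOut, wOut) {
  d <- dim(pixels)
  if (hOut == d[1] && wOut == d[2]) return(pixels)
  Wy <- .boxWeights(d[1], hOut)
  Wx <- .boxWeights(d[2], wOut)
  out <- array(0, c(hOut, wOut, 3L))
  for (ch in 1:3) out[, , ch] <- Wy %*% pixels[, , ch] %*% t(Wx)
  out
}

#' Downscale a section before tiling
#'
#' The grading pipeline downscales scanned sections by 50% before
#' splitting them into tiles. Resampling is area averaging (box filter,
#' anti-aliased); output dimensions are \code{round(dim * factor)} with
#' half away from zero and a minimum of 1, and the microns-per-pixel
#' metadata is divided by the factor.
#'
#' @param section a [SectionImage-class].
#' @param factor scale in (0, 1]; 1 returns the input unchanged. Default
#'   0.5, the pipeline constant.
#' @return The downscaled [SectionImage-class].
#' @export
downscaleSection <- function(section, factor = 0.5) {
  .assertScalarNumber(factor, "factor")
  if (factor <= 0 || factor > 1)
    stop("factor must be in (0, 1]", call. = FALSE)
  if (factor == 1) return(section)
  d <- dim(section@pixels)
  hOut <- max(1L, as.integer(.roundHalfUp(d[1] * factor)))
  wOut <- max(1L, as.integer(.roundHalfUp(d[2] * factor)))
  new("SectionImage", pixels = .resizeArea(section@pixels, hOut, wOut),
      mpp = section@mpp / factor, stain = section@stain,
      ident = section@ident)
}

#' Build a tissue/background mask for a section
#'
#' A pixel counts as tissue when its BT.601 luminance falls below the
#' white-background threshold or its HSV saturation rises above the
#' saturation threshold; slide background (bright, unsaturated glass)
#' fails both. Thresholds are fractions of full scale.
#'
#' @param section a [SectionImage-class].
#' @param luminanceThreshold tissue if luminance < this (default 0.92).
#' @param saturationThreshold tissue if saturation > this (default 0.08).
#' @return A [TissueMask-class] congruent with the section.
#' @export
tissueMask <- function(section, luminanceThreshold = 0.92,
                       saturationThreshold = 0.08) {
  px <- section@pixels
  m <- .luminance(px) < luminanceThreshold | .saturation(px) > saturationThreshold
  new("TissueMask", mask = m,
      params = list(luminanceThreshold = luminanceThreshold,
                    saturationThreshold = saturationThreshold))
}

#' Split a (downscaled) section into scoring tiles
#'
#' Lays a row-major grid of \code{tileSize x tileSize} tiles over the
#' section: \code{ceiling(h / tileSize) x ceiling(w / tileSize)} positions,
#' 0-based half-open coordinates. Edge tiles are padded with background
#' white and record the in-bounds \code{valid_fraction}. Tiles whose
#' tissue fraction (tissue pixels over the full tile footprint) falls
#' below \code{minTissueFraction} are flagged excluded-from-scoring but
#' kept in the grid so heatmaps stay congruent with the section.
#'
#' @param section a [SectionImage-class], already downscaled.
#' @param tileSize tile side in pixels (default 512, the pipeline
#'   constant).
#' @param minTissueFraction exclusion threshold on tile tissue content
#'   (default 0.05).
#' @param mask optional precomputed [TissueMask-class]; computed with
#'   default thresholds when missing.
#' @return A [TileGrid-class].
#' @export
tileSection <- function(section, tileSize = 512L, minTissueFraction = 0.05,
                        mask = NULL) {
  tileSize <- as.integer(tileSize)
  if (is.na(tileSize) || tileSize < 1L)
    stop("tileSize must be >= 1", call. = FALSE)
  if (is.null(mask)) mask <- tissueMask(section)
  px <- section@pixels
  d <- dim(px)
  h <- d[1]; w <- d[2]
  if (!identical(dim(mask@mask), d[1:2]))
    stop("mask is not congruent with the section", call. = FALSE)
  nR <- ceiling(h / tileSize)
  nC <- ceiling(w / tileSize)
  n <- nR * nC
  tiles <- vector("list", n)
  man <- data.frame(ident = rep(section@ident, n), row = integer(n),
                    col = integer(n), y0 = integer(n), x0 = integer(n),
                    tile_size = rep(tileSize, n),
                    valid_fraction = numeric(n), tissue_fraction = numeric(n),
                    excluded = logical(n), stringsAsFactors = FALSE)
  k <- 0L
  for (r in seq_len(nR)) {
    for (cc in seq_len(nC)) {
      k <- k + 1L
      y0 <- (r - 1L) * tileSize
      x0 <- (cc - 1L) * tileSize
      hv <- min(tileSize, h - y0)
      wv <- min(tileSize, w - x0)
      tile <- array(255, c(tileSize, tileSize, 3L))
      tile[seq_len(hv), seq_len(wv), ] <-
        px[y0 + seq_len(hv), x0 + seq_len(wv), , drop = FALSE]
      nTissue <- sum(mask@mask[y0 + seq_len(hv), x0 + seq_len(wv)])
      tf <- nTissue / (tileSize * tileSize)
      tiles[[k]] <- tile
      man$row[k] <- r - 1L; man$col[k] <- cc - 1L
      man$y0[k] <- y0; man$x0[k] <- x0
      man$valid_fraction[k] <- (hv * wv) / (tileSize * tileSize)
      man$tissue_fraction[k] <- tf
      man$excluded[k] <- tf < minTissueFraction
    }
  }
  new("TileGrid", tileSize = tileSize, sectionDim = c(h, w),
      manifest = man, tiles = tiles, ident = section@ident)
}

#' Reassemble a tiled section from its grid
#'
#' Inverse of [tileSection()]: places each tile's valid (unpadded) region
#' back at its grid position. Round-trips the downscaled section
#' bit-exactly.
#'
#' @param grid a [TileGrid-class].
#' @param stain,mpp metadata for the rebuilt [SectionImage-class].
#' @return A [SectionImage-class].
#' @export
reassembleSection <- function(grid, stain = "synthetic", mpp = NA_real_) {
  h <- grid@sectionDim[1]; w <- grid@sectionDim[2]
  out <- array(0, c(h, w, 3L))
  m <- grid@manifest
  for (k in seq_len(nrow(m))) {
    hv <- min(grid@tileSize, h - m$y0[k])
    wv <- min(grid@tileSize, w - m$x0[k])
    out[m$y0[k] + seq_len(hv), m$x0[k] + seq_len(wv), ] <-
      grid@tiles[[k]][seq_len(hv), seq_len(wv), , drop = FALSE]
  }
  sectionImage(out, mpp = mpp, stain = stain, ident = grid@ident)
}

#' Write a tile manifest as TSV
#'
#' Columns: ident, row, col, y0, x0, tile_size, valid_fraction,
#' tissue_fraction, excluded (0/1).
#'
#' @param grid a [TileGrid-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTileManifest <- function(grid, path) {
  m <- grid@manifest
  m$excluded <- as.integer(m$excluded)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
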