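## Whole-section composite Ashcroft score, group-wise grade
## distributions, and per-tile grade heatmaps.

#' Composite whole-section Ashcroft score
#'
#' The tile-count-weighted mean grade over included tiles,
#' \deqn{(0 n_0 + 1 n_1 + \dots + 8 n_8) / (n_0 + \dots + n_8),}
#' where \eqn{n_g} counts the tiles of grade \eqn{g}. Excluded tiles
#' (non-alveolar predictions and low-tissue tiles) are tallied in
#' \code{nExcluded} and never enter numerator or denominator. A map with
#' no included tiles is an error, not a score of 0.
#'
#' @param map a [TileGradeMap-class].
#' @return A [CompositeScore-class].
#' @export
#' @examples
#' m <- tileGradeMap(matrix(c(0, 0, 2, 8), 2, 2))
#' scoreValue(compositeScore(m))  # (0 + 0 + 2 + 8) / 4
compositeScore <- function(map) {
  inc <- !map@excluded
  grades <- suppressWarnings(as.numeric(map@labels[inc]))
  grades <- grades[!is.na(grades)]
  if (length(grades) == 0L)
    stop("no included tiles: the composite score is undefined",
         call. = FALSE)
  counts <- vapply(0:8, function(g) sum(grades == g), numeric(1))
  names(counts) <- paste0("n", 0:8)
  value <- sum((0:8) * counts) / sum(counts)
  new("CompositeScore", value = value, counts = counts,
      nExcluded = as.integer(length(map@labels) - length(grades)),
      ident = map@ident)
}

#' Group-wise distribution of tile grades
#'
#' Pools the included tiles of each group's sections and reports per-grade
#' counts and proportions (proportions sum to 1 within each group).
#'
#' @param maps list of [TileGradeMap-class].
#' @param groups group label per map (e.g. treatment arm).
#' @return data.frame with columns \code{group}, \code{grade},
#'   \code{count}, \code{proportion}.
#' @export
scoreDistribution <- function(maps, groups) {
  if (length(maps) != length(groups))
    stop("groups must match maps in length", call. = FALSE)
  if (length(maps) == 0L) stop("no grade maps", call. = FALSE)
  out <- NULL
  for (g in unique(groups)) {
    sel <- maps[groups == g]
    counts <- numeric(9)
    for (m in sel) {
      grades <- suppressWarnings(as.numeric(m@labels[!m@excluded]))
      grades <- grades[!is.na(grades)]
      counts <- counts + vapply(0:8, function(k) sum(grades == k),
                                numeric(1))
    }
    if (sum(counts) == 0)
      stop("group '", g, "' has no included tiles", call. = FALSE)
    out <- rbind(out, data.frame(group = g, grade = 0:8, count = counts,
                                 proportion = counts / sum(counts)))
  }
  rownames(out) <- NULL
  out
}

## Grade colour ramp: linear interpolation from dark indigo to yellow.
## Every channel is strictly increasing in the grade, so ramp luminance
## is strictly monotone - the documented contract for heatmap reading.
.gradeRamp <- function() {
  lo <- c(26, 11, 64)
  hi <- c(245, 215, 66)
  t(vapply(0:8, function(g) lo + (hi - lo) * g / 8, numeric(3)))
}

.excludedColor <- c(150, 150, 150)

#' Render a per-tile grade heatmap
#'
#' One coloured block per tile: grades follow a strictly monotone dark
#' indigo to yellow ramp, excluded tiles are neutral gray. With
#' \code{section} supplied, the heatmap is rendered at tile resolution
#' and alpha-blended over the section raster instead.
#'
#' @param map a [TileGradeMap-class].
#' @param blockSize rendered pixels per tile (ignored when overlaying).
#' @param section optional [SectionImage-class] congruent with the map's
#'   grid for an overlay rendering.
#' @param alpha overlay opacity of the grade colour in [0, 1].
#' @return A [HeatmapRaster-class].
#' @export
renderHeatmap <- function(map, blockSize = 16L, section = NULL,
                          alpha = 0.45) {
  ramp <- .gradeRamp()
  nR <- nrow(map@labels); nC <- ncol(map@labels)
  colorOf <- function(r, cc) {
    if (map@excluded[r, cc]) return(.excludedColor)
    g <- suppressWarnings(as.integer(map@labels[r, cc]))
    if (is.na(g)) return(.excludedColor)
    ramp[g + 1L, ]
  }
  legend <- data.frame(grade = c(as.character(0:8), "excluded"),
                       r = c(ramp[, 1], .excludedColor[1]),
                       g = c(ramp[, 2], .excludedColor[2]),
                       b = c(ramp[, 3], .excludedColor[3]))
  if (!is.null(section)) {
    ts <- map@tileSize
    d <- dim(section@pixels)
    if (nR != ceiling(d[1] / ts) || nC != ceiling(d[2] / ts))
      stop("grade map is not aligned with the section's tile grid",
           call. = FALSE)
    out <- section@pixels
    for (r in seq_len(nR)) for (cc in seq_len(nC)) {
      ys <- ((r - 1L) * ts + 1L):min(r * ts, d[1])
      xs <- ((cc - 1L) * ts + 1L):min(cc * ts, d[2])
      col <- colorOf(r, cc)
      for (ch in 1:3)
        out[ys, xs, ch] <- (1 - alpha) * out[ys, xs, ch] + alpha * col[ch]
    }
    return(new("HeatmapRaster", raster = out, legend = legend,
               blockSize = as.integer(ts)))
  }
  blockSize <- as.integer(blockSize)
  out <- array(0, c(nR * blockSize, nC * blockSize, 3L))
  for (r in seq_len(nR)) for (cc in seq_len(nC)) {
    col <- colorOf(r, cc)
    ys <- ((r - 1L) * blockSize + 1L):(r * blockSize)
    xs <- ((cc - 1L) * blockSize + 1L):(cc * blockSize)
    for (ch in 1:3) out[ys, xs, ch] <- col[ch]
  }
  new("HeatmapRaster", raster = out, legend = legend,
      blockSize = blockSize)
}

#' Write a heatmap raster (PNG) and its legend (JSON)
#'
#' @param heatmap a [HeatmapRaster-class].
#' @param path output PNG path; the legend goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeHeatmap <- function(heatmap, path) {
  png::writePNG(pmin(pmax(heatmap@raster, 0), 255) / 255, path)
  jsonlite::write_json(heatmap@legend, paste0(path, ".json"),
                       digits = NA)
  invisible(path)
}

#' Write composite scores as TSV
#'
#' Columns: ident, score, n0..n8, n_excluded, n_total.
#'
#' @param scores list of [CompositeScore-class] (or a single one).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeScoresTSV <- function(scores, path) {
  if (is(scores, "CompositeScore")) scores <- list(scores)
  rows <- lapply(scores, function(s) {
    cbind(data.frame(ident = s@ident, score = s@value),
          as.data.frame(as.list(s@counts)),
          data.frame(n_excluded = s@nExcluded,
                     n_total = sum(s@counts) + s@nExcluded))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score a section end to end
#'
#' Convenience wrapper for the full pipeline on one raster: downscale,
#' tile, predict per-tile grades, aggregate.
#'
#' @param section a [SectionImage-class] (full resolution).
#' @param model a trained [ClassifierModel-class].
#' @param downscale pre-tiling scale factor (default 0.5).
#' @param tileSize tile side after downscaling (default 512).
#' @param minTissueFraction exclusion threshold, see [tileSection()].
#' @return List with \code{score} ([CompositeScore-class]), \code{map}
#'   ([TileGradeMap-class]) and \code{grid} ([TileGrid-class]).
#' @export
scoreSection <- function(section, model, downscale = 0.5, tileSize = 512L,
                         minTissueFraction = 0.05) {
  small <- downscaleSection(section, downscale)
  grid <- tileSection(small, tileSize = tileSize,
                      minTissueFraction = minTissueFraction)
  map <- predictGrades(model, grid)
  list(score = compositeScore(map), map = map, grid = grid)
}
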