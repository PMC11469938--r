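## Generics and accessors. Slot access from user code goes through these.

#' Predict class probabilities for tile rasters
#'
#' @param model a [ClassifierModel-class].
#' @param tiles a single tile raster (\code{s x s x 3} array), a
#'   [LabeledTile-class], or a list of either.
#' @return numeric matrix, one row per tile, one column per class in
#'   \code{classLabels(model)} order; rows sum to 1.
#' @export
setGeneric("predictTile", function(model, tiles) standardGeneric("predictTile"))

#' @rdname accessors
#' @export
setGeneric("sectionPixels", function(x) standardGeneric("sectionPixels"))
#' @rdname accessors
#' @export
setGeneric("micronsPerPixel", function(x) standardGeneric("micronsPerPixel"))
#' @rdname accessors
#' @export
setGeneric("sectionIdent", function(x) standardGeneric("sectionIdent"))
#' @rdname accessors
#' @export
setGeneric("tileManifest", function(x) standardGeneric("tileManifest"))
#' @rdname accessors
#' @export
setGeneric("tilePixels", function(x, i) standardGeneric("tilePixels"))
#' @rdname accessors
#' @export
setGeneric("tileLabels", function(x) standardGeneric("tileLabels"))
#' @rdname accessors
#' @export
setGeneric("excludedTiles", function(x) standardGeneric("excludedTiles"))
#' @rdname accessors
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))
#' @rdname accessors
#' @export
setGeneric("gradeCounts", function(x) standardGeneric("gradeCounts"))
#' @rdname accessors
#' @export
setGeneric("kappaValue", function(x) standardGeneric("kappaValue"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("accuracyTrace", function(x) standardGeneric("accuracyTrace"))
#' @rdname accessors
#' @export
setGeneric("areaPercent", function(x) standardGeneric("areaPercent"))
#' @rdname accessors
#' @export
setGeneric("volumeMl", function(x) standardGeneric("volumeMl"))

#' Accessors for fibrotile classes
#'
#' Small read-only accessors: \code{sectionPixels} and
#' \code{micronsPerPixel} for [SectionImage-class]; \code{tileManifest}
#' and \code{tilePixels} for [TileGrid-class]; \code{tileLabels} and
#' \code{excludedTiles} for [TileGradeMap-class]; \code{scoreValue} and
#' \code{gradeCounts} for [CompositeScore-class]; \code{kappaValue} for
#' [KappaResult-class]; \code{classLabels} and \code{accuracyTrace} for
#' classifier models; \code{areaPercent} for [AreaFraction-class];
#' \code{volumeMl} for [LobuleVolume-class] and [MarkerVolume-class].
#'
#' @param x the object.
#' @param i tile index (row-major) for \code{tilePixels}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("sectionPixels", "SectionImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("micronsPerPixel", "SectionImage", function(x) x@mpp)
#' @rdname accessors
#' @export
setMethod("sectionIdent", "SectionImage", function(x) x@ident)
#' @rdname accessors
#' @export
setMethod("tileManifest", "TileGrid", function(x) x@manifest)
#' @rdname accessors
#' @export
setMethod("tilePixels", "TileGrid", function(x, i) x@tiles[[i]])
#' @rdname accessors
#' @export
setMethod("tileLabels", "TileGradeMap", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("excludedTiles", "TileGradeMap", function(x) x@excluded)
#' @rdname accessors
#' @export
setMethod("scoreValue", "CompositeScore", function(x) x@value)
#' @rdname accessors
#' @export
setMethod("gradeCounts", "CompositeScore", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("kappaValue", "KappaResult", function(x) x@kappa)
#' @rdname accessors
#' @export
setMethod("classLabels", "ClassifierModel", function(x) x@classes)
#' @rdname accessors
#' @export
setMethod("accuracyTrace", "SmallCNNClassifier", function(x) x@trace)
#' @rdname accessors
#' @export
setMethod("areaPercent", "AreaFraction", function(x) x@percent)
#' @rdname accessors
#' @export
setMethod("volumeMl", "LobuleVolume", function(x) x@volumeMl)
#' @rdname accessors
#' @export
setMethod("volumeMl", "MarkerVolume", function(x) x@volumeMl)

setMethod("show", "SectionImage", function(object) {
  d <- dim(object@pixels)
  cat("SectionImage '", object@ident, "': ", d[1], " x ", d[2],
      " px, stain ", object@stain,
      if (!is.na(object@mpp)) paste0(", ", format(object@mpp), " um/px"),
      "\n", sep = "")
})

setMethod("show", "TileGrid", function(object) {
  m <- object@manifest
  cat("TileGrid '", object@ident, "': ", max(m$row) + 1L, " x ",
      max(m$col) + 1L, " tiles of ", object@tileSize, " px (",
      sum(m$excluded), " excluded)\n", sep = "")
})

setMethod("show", "TileGradeMap", function(object) {
  cat("TileGradeMap '", object@ident, "': ", nrow(object@labels), " x ",
      ncol(object@labels), " tiles, ", sum(object@excluded),
      " excluded\n", sep = "")
})

setMethod("show", "CompositeScore", function(object) {
  cat("CompositeScore '", object@ident, "': ",
      format(object@value, digits = 4), " (", sum(object@counts),
      " tiles included, ", object@nExcluded, " excluded)\n", sep = "")
})

setMethod("show", "KappaResult", function(object) {
  cat("Cohen's kappa (", object@weighting, "): ",
      format(object@kappa, digits = 4), "  [pO = ",
      format(object@pO, digits = 4), ", pE = ",
      format(object@pE, digits = 4), ", N = ", object@N, "]",
      if (object@degenerate) "  (degenerate pE = 1)", "\n", sep = "")
})

setMethod("show", "CentroidClassifier", function(object) {
  cat("CentroidClassifier: ", nrow(object@centroids), " classes x ",
      ncol(object@centroids), " texture features\n", sep = "")
})

setMethod("show", "SmallCNNClassifier", function(object) {
  cat("SmallCNNClassifier: input ", object@inputSize, " x ",
      object@inputSize, ", ", length(object@trace), " epochs, best val acc ",
      format(max(object@trace), digits = 4), "\n", sep = "")
})

setMethod("show", "LobuleVolume", function(object) {
  cat("LobuleVolume: ", format(object@volumeMl, digits = 6), " mL (",
      object@massG, " g / ", object@density, " g/mL)\n", sep = "")
})

setMethod("show", "MarkerVolume", function(object) {
  cat("MarkerVolume: ", format(object@volumeMl, digits = 6),
      " mL (mean ", format(object@meanPercent, digits = 4), "% of ",
      format(object@lobule@volumeMl, digits = 6), " mL)\n", sep = "")
})
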