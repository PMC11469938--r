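## S4 classes for the grading pipeline. Conventions used throughout:
## rasters are numeric arrays h x w x 3 with channel values in [0, 255];
## grid coordinates are 0-based, half-open, (row, col) = (y, x).

#' Class labels of the tile classifier
#'
#' The ordinal Ashcroft grades \code{"0"} to \code{"8"} (normal alveolar
#' architecture through total fibrous obliteration) followed by the
#' \code{"non_alveolar"} class used for large bronchi and vessels, which is
#' excluded from composite scoring.
#'
#' @return Character vector of the 10 class labels in canonical order.
#' @export
#' @examples
#' gradeLevels()
gradeLevels <- function() c(as.character(0:8), "non_alveolar")

#' Label of the non-alveolar tile class
#' @return The character label used for non-alveolar tiles.
#' @export
nonAlveolarLabel <- function() "non_alveolar"

#' SectionImage: an RGB histology raster
#'
#' The unit of ingestion: a whole-section RGB raster with optional
#' microns-per-pixel metadata, a stain label and a sample identifier.
#'
#' @slot pixels numeric array \code{h x w x 3}, channel values in [0, 255].
#' @slot mpp microns per pixel (\code{NA_real_} if unknown; must be > 0).
#' @slot stain stain label, one of \code{stainLabels()}.
#' @slot ident sample identifier.
#' @export
setClass("SectionImage",
  representation(pixels = "array", mpp = "numeric", stain = "character",
                 ident = "character"))

#' Recognised stain labels
#' @return Character vector of stain labels accepted by [SectionImage-class].
#' @export
stainLabels <- function()
  c("MT", "PSR", "IHC-Col1a1", "IHC-Col3", "IHC-aSMA", "IHC-Gal3", "synthetic")

setValidity("SectionImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be an h x w x 3 array")
  if (d[1] < 1L || d[2] < 1L) return("height and width must be >= 1")
  if (anyNA(object@pixels)) return("pixels must not contain NA")
  rng <- range(object@pixels)
  if (rng[1] < 0 || rng[2] > 255) return("channel values must be in [0, 255]")
  if (length(object@mpp) != 1L) return("mpp must be length 1")
  if (!is.na(object@mpp) && object@mpp <= 0) return("mpp must be > 0")
  if (!object@stain %in% stainLabels())
    return(paste0("unknown stain '", object@stain, "'"))
  TRUE
})

#' TissueMask: binary tissue/background mask congruent with a section
#'
#' @slot mask logical matrix, \code{TRUE} where a pixel is tissue.
#' @slot params list recording the thresholds used to build the mask.
#' @export
setClass("TissueMask", representation(mask = "matrix", params = "list"))

setValidity("TissueMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

#' TileGrid: the tiling of a downscaled section
#'
#' Row-major grid of \code{tileSize x tileSize} tiles covering a section.
#' Edge tiles are padded with background white; \code{validFraction} records
#' the in-bounds area and \code{tissueFraction} the tissue content, and tiles
#' under the tissue threshold are flagged \code{excluded} (they stay in the
#' grid so heatmaps remain congruent with the section).
#'
#' @slot tileSize tile side length in pixels.
#' @slot sectionDim integer height, width of the tiled section.
#' @slot manifest data.frame with one row per tile: \code{ident, row, col,
#'   y0, x0, tile_size, valid_fraction, tissue_fraction, excluded}
#'   (0-based \code{row}/\code{col}/\code{y0}/\code{x0}).
#' @slot tiles list of tile pixel arrays in row-major order.
#' @slot ident section identifier.
#' @export
setClass("TileGrid",
  representation(tileSize = "integer", sectionDim = "integer",
                 manifest = "data.frame", tiles = "list", ident = "character"))

setValidity("TileGrid", function(object) {
  if (object@tileSize < 1L) return("tileSize must be >= 1")
  if (nrow(object@manifest) != length(object@tiles))
    return("manifest and tiles disagree in length")
  vf <- object@manifest$valid_fraction
  if (any(vf <= 0 | vf > 1)) return("valid_fraction must be in (0, 1]")
  tf <- object@manifest$tissue_fraction
  if (any(tf < 0 | tf > 1)) return("tissue_fraction must be in [0, 1]")
  TRUE
})

#' LabeledTile: a tile raster with its ground-truth class
#'
#' @slot pixels numeric array \code{s x s x 3} in [0, 255].
#' @slot label class label, one of \code{gradeLevels()}.
#' @slot seed RNG seed the tile was generated with (\code{NA} for real data).
#' @export
setClass("LabeledTile",
  representation(pixels = "array", label = "character", seed = "integer"))

setValidity("LabeledTile", function(object) {
  if (!object@label %in% gradeLevels())
    return(paste0("unknown label '", object@label, "'"))
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) return("pixels must be s x s x 3")
  TRUE
})

#' TileGradeMap: per-tile class assignments on a tile grid
#'
#' Holds one label per grid tile plus the excluded flags (non-alveolar
#' predictions and low-tissue tiles) and, optionally, the per-tile class
#' probability vectors. Excluded tiles never contribute to the composite
#' score.
#'
#' @slot labels character matrix (grid rows x cols) of class labels.
#' @slot excluded logical matrix, same shape, \code{TRUE} for tiles excluded
#'   from scoring.
#' @slot probs numeric matrix (n tiles x 10, row-major tile order) of class
#'   probabilities, or a 0-row matrix when unavailable.
#' @slot tileSize tile side length in pixels.
#' @slot ident section identifier.
#' @export
setClass("TileGradeMap",
  representation(labels = "matrix", excluded = "matrix", probs = "matrix",
                 tileSize = "integer", ident = "character"))

setValidity("TileGradeMap", function(object) {
  if (!identical(dim(object@labels), dim(object@excluded)))
    return("labels and excluded must have identical shape")
  bad <- !object@labels %in% gradeLevels()
  if (any(bad)) return("labels must be grades 0-8 or non_alveolar")
  if (nrow(object@probs) > 0 && nrow(object@probs) != length(object@labels))
    return("probs must have one row per tile")
  TRUE
})

#' CompositeScore: the whole-section Ashcroft score
#'
#' The tile-count-weighted mean grade \eqn{(\sum_g g\,n_g)/(\sum_g n_g)}
#' over included tiles, together with the per-grade tile counts.
#'
#' @slot value composite score in [0, 8].
#' @slot counts named numeric vector \code{n0 ... n8} of included tile
#'   counts per grade.
#' @slot nExcluded number of excluded tiles (non-alveolar + low tissue).
#' @slot ident section identifier.
#' @export
setClass("CompositeScore",
  representation(value = "numeric", counts = "numeric",
                 nExcluded = "integer", ident = "character"))

setValidity("CompositeScore", function(object) {
  if (length(object@counts) != 9L) return("counts must have 9 entries")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  if (object@value < 0 || object@value > 8) return("value must be in [0, 8]")
  TRUE
})

#' HeatmapRaster: per-tile grade colours for a section
#'
#' @slot raster numeric array (rows*block x cols*block x 3) in [0, 255].
#' @slot legend data.frame mapping each grade to its ramp colour.
#' @slot blockSize rendered pixels per tile.
#' @export
setClass("HeatmapRaster",
  representation(raster = "array", legend = "data.frame",
                 blockSize = "integer"))

#' KappaResult: Cohen's kappa with its components
#'
#' @slot kappa chance-corrected agreement in [-1, 1].
#' @slot pO observed (possibly weighted) agreement.
#' @slot pE chance agreement from the marginals.
#' @slot weighting \code{"none"}, \code{"linear"} or \code{"quadratic"}.
#' @slot N total number of paired items.
#' @slot degenerate \code{TRUE} when pE = 1 and the usual formula is
#'   undefined (kappa is then 1 if pO = 1, else 0).
#' @export
setClass("KappaResult",
  representation(kappa = "numeric", pO = "numeric", pE = "numeric",
                 weighting = "character", N = "numeric",
                 degenerate = "logical"))

setValidity("KappaResult", function(object) {
  if (object@pO < -1e-12 || object@pO > 1 + 1e-12) return("pO must be in [0, 1]")
  if (object@pE < -1e-12 || object@pE > 1 + 1e-12) return("pE must be in [0, 1]")
  if (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)
    return("kappa must be in [-1, 1]")
  TRUE
})

#' TextureParams: controls of the synthetic tile generator
#'
#' The generator is a surrogate for graded fibrotic remodelling: an
#' alveolar lattice whose wall thickness and collagen-coloured fibrotic
#' mass fraction both increase monotonically with grade, so the 0-8 scale
#' is ordinal and learnable by texture.
#'
#' @slot palette 3 x 3 numeric matrix; rows \code{airspace}, \code{tissue},
#'   \code{collagen} give the base RGB of each pixel class.
#' @slot wallThickness 9 strictly increasing alveolar-wall thicknesses
#'   (pixels), grades 0..8.
#' @slot massFraction 9 strictly increasing fibrotic-mass area targets in
#'   [0, 1]; grade 0 is 0 and grade 8 at least 0.95.
#' @slot noiseSd per-channel Gaussian noise sd (8-bit counts).
#' @slot seed default seed used when an operation is not given one.
#' @export
setClass("TextureParams",
  representation(palette = "matrix", wallThickness = "numeric",
                 massFraction = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("TextureParams", function(object) {
  if (!identical(dim(object@palette), c(3L, 3L)))
    return("palette must be a 3 x 3 RGB matrix")
  if (any(object@palette < 0 | object@palette > 255))
    return("palette values must be in [0, 255]")
  if (length(object@wallThickness) != 9L || length(object@massFraction) != 9L)
    return("per-grade sequences must have 9 entries (grades 0..8)")
  if (any(diff(object@wallThickness) <= 0))
    return("wallThickness must be strictly increasing")
  if (any(diff(object@massFraction) <= 0))
    return("massFraction must be strictly increasing")
  if (object@massFraction[1] != 0) return("massFraction[grade 0] must be 0")
  if (object@massFraction[9] < 0.95)
    return("massFraction[grade 8] must be >= 0.95")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})

#' SplitFractions: train/validation/test proportions
#'
#' @slot train,validation,test fractions in [0, 1] summing to 1
#'   (default 0.75 / 0.20 / 0.05).
#' @export
setClass("SplitFractions",
  representation(train = "numeric", validation = "numeric", test = "numeric"))

setValidity("SplitFractions", function(object) {
  f <- c(object@train, object@validation, object@test)
  if (any(f < 0 | f > 1)) return("fractions must be in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1")
  TRUE
})

#' DatasetSplit: disjoint train/validation/test tile partitions
#'
#' @slot train,validation,test lists of [LabeledTile-class].
#' @export
setClass("DatasetSplit",
  representation(train = "list", validation = "list", test = "list"))

#' Virtual parent of tile classifiers
#'
#' A classifier maps a tile raster to a probability vector over the 10
#' classes of \code{gradeLevels()}. \code{metadata} records architecture,
#' seed and the per-epoch validation accuracy trace where applicable.
#' @slot classes class labels in probability-column order.
#' @slot metadata list of descriptive metadata.
#' @export
setClass("ClassifierModel",
  representation("VIRTUAL", classes = "character", metadata = "list"))

#' Nearest-centroid texture baseline classifier
#'
#' Deterministic, training-free baseline: tiles are embedded in a fixed
#' texture-feature space (collagen fraction, tissue fraction, mean
#' luminance, edge density, ring score) and classified by nearest class
#' centroid.
#' @slot centroids class x feature matrix of standardized centroids.
#' @slot featureCenter,featureScale standardization of the feature space.
#' @slot palette palette used for palette-fraction features.
#' @export
setClass("CentroidClassifier", contains = "ClassifierModel",
  representation(centroids = "matrix", featureCenter = "numeric",
                 featureScale = "numeric", palette = "matrix"))

#' Small reference convolutional network
#'
#' Three conv(3x3)/ReLU/max-pool blocks (8, 16, 32 filters) on tiles
#' resized to 32 x 32, a 64-unit dense layer and a 10-way softmax;
#' trained with Adam on softmax cross-entropy.
#' @slot weights list of layer weight arrays.
#' @slot inputSize side length the input is resized to.
#' @slot trace per-epoch validation accuracy.
#' @export
setClass("SmallCNNClassifier", contains = "ClassifierModel",
  representation(weights = "list", inputSize = "integer", trace = "numeric"))

#' AreaFraction: positive-pixel staining fraction of a section
#'
#' @slot percent positive pixels as % of tissue area, in [0, 100].
#' @slot nPositive,nTissue pixel counts behind the percentage.
#' @slot ident section identifier.
#' @export
setClass("AreaFraction",
  representation(percent = "numeric", nPositive = "numeric",
                 nTissue = "numeric", ident = "character"))

setValidity("AreaFraction", function(object) {
  if (object@percent < 0 || object@percent > 100)
    return("percent must be in [0, 100]")
  TRUE
})

#' LobuleVolume: lung-lobe volume from fluid displacement
#'
#' Archimedes principle: volume (mL) = displaced fluid mass (g) / fluid
#' density (g/mL).
#' @slot volumeMl volume in mL.
#' @slot massG displaced-fluid mass in grams.
#' @slot density fluid density in g/mL.
#' @export
setClass("LobuleVolume",
  representation(volumeMl = "numeric", massG = "numeric", density = "numeric"))

setValidity("LobuleVolume", function(object) {
  if (object@volumeMl <= 0) return("volume must be > 0")
  TRUE
})

#' MarkerVolume: whole-lobule stained-marker volume
#'
#' Mean serial-section %-area of a marker times the lobule volume.
#' @slot volumeMl marker volume (mean %-area / 100 x lobule volume), mL.
#' @slot singleSectionMl estimate from the designated single section, mL.
#' @slot meanPercent mean %-area across serial sections.
#' @slot lobule the [LobuleVolume-class] used.
#' @export
setClass("MarkerVolume",
  representation(volumeMl = "numeric", singleSectionMl = "numeric",
                 meanPercent = "numeric", lobule = "LobuleVolume"))
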