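## Training-data assembly and tile-grade prediction: class balancing by
## resampling, stratified 75/20/5 splitting, augmentation (rotations,
## flips, brightness), the deterministic texture baseline, and grade-map
## prediction over a tile grid.

#' Train/validation/test split fractions
#'
#' Defaults to the pipeline's 75% / 20% / 5% split.
#'
#' @param train,validation,test fractions in [0, 1]; must sum to 1.
#' @return A [SplitFractions-class].
#' @export
splitFractions <- function(train = 0.75, validation = 0.20, test = 0.05) {
  new("SplitFractions", train = train, validation = validation, test = test)
}

#' Training configuration for the tile classifier
#'
#' @param epochs number of training epochs (default 25, the pipeline
#'   constant).
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize minibatch size (default 32).
#' @param augment named logical switches \code{rotations}, \code{flips},
#'   \code{brightness}.
#' @param brightnessRange half-width of the multiplicative brightness
#'   augmentation; the factor is drawn uniformly from
#'   \code{[1 - range, 1 + range]} (default 0.2).
#' @param architecture \code{"reference_small_cnn"} (the built-in small
#'   network) or \code{"inception_v3"}; the latter needs a deep-learning
#'   backend and is rejected at training time in this build.
#' @param seed seed controlling initialisation, shuffling and
#'   augmentation.
#' @param inputSize side length tiles are resized to before entering the
#'   network (default 32; must be a multiple of 8).
#' @return A list of class \code{"trainingConfig"}.
#' @export
trainingConfig <- function(epochs = 25L, learningRate = 1e-3,
                           batchSize = 32L,
                           augment = c(rotations = TRUE, flips = TRUE,
                                       brightness = TRUE),
                           brightnessRange = 0.2,
                           architecture = c("reference_small_cnn",
                                            "inception_v3"),
                           seed = 1L, inputSize = 32L) {
  epochs <- as.integer(epochs)
  batchSize <- as.integer(batchSize)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (is.na(batchSize) || batchSize < 1L)
    stop("batchSize must be >= 1", call. = FALSE)
  inputSize <- as.integer(inputSize)
  if (inputSize < 8L || inputSize %% 8L != 0L)
    stop("inputSize must be a positive multiple of 8", call. = FALSE)
  cfg <- list(epochs = epochs, learningRate = learningRate,
              batchSize = batchSize,
              augment = augment, brightnessRange = brightnessRange,
              architecture = match.arg(architecture),
              seed = as.integer(seed), inputSize = inputSize,
              classes = gradeLevels())
  class(cfg) <- "trainingConfig"
  cfg
}

.tileLabel <- function(tile) tile@label

#' Oversample minority classes to the majority count
#'
#' Every represented class is resampled with replacement up to the
#' majority-class count. Output tiles are copies of input tiles only —
#' no pixels are fabricated. Originals keep their position; duplicates
#' are appended.
#'
#' @param tiles list of [LabeledTile-class].
#' @param seed RNG seed for the resampling draws.
#' @return List of [LabeledTile-class] with equal per-class counts.
#' @export
balanceByResampling <- function(tiles, seed = 1L) {
  if (length(tiles) == 0L) stop("no tiles to balance", call. = FALSE)
  labels <- vapply(tiles, .tileLabel, "")
  counts <- table(labels)
  target <- max(counts)
  extra <- integer(0)
  seeds <- .deriveSeeds(seed, length(counts))
  for (i in seq_along(counts)) {
    idx <- which(labels == names(counts)[i])
    deficit <- target - length(idx)
    if (deficit > 0L)
      extra <- c(extra, .withSeed(seeds[i],
                                  sample(idx, deficit, replace = TRUE)))
  }
  c(tiles, tiles[extra])
}

## Largest-remainder apportionment of n items over fractions.
## Ties in the remainders go to the larger fraction, then to the earlier
## position, so the result is deterministic.
.largestRemainder <- function(n, fracs) {
  q <- n * fracs
  base <- floor(q)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    ord <- order(-(q - base), -fracs, seq_along(fracs))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Splits tiles per class with largest-remainder apportionment of the
#' fractions, so each class's split sizes are within one tile of exact
#' proportionality. Assignment within a class is a seeded shuffle. Tiles
#' are unique across partitions: balancing (oversampling) is applied
#' afterwards, to the training partition only, so duplicates can never
#' leak across split boundaries.
#'
#' @param tiles list of [LabeledTile-class].
#' @param fractions a [SplitFractions-class].
#' @param seed RNG seed.
#' @param groupIds optional vector (one per tile, e.g. section idents);
#'   when given, whole groups are assigned to one partition to prevent
#'   intra-section leakage, with group-level largest-remainder
#'   apportionment instead of class stratification.
#' @return A [DatasetSplit-class].
#' @export
stratifiedSplit <- function(tiles, fractions = splitFractions(), seed = 1L,
                            groupIds = NULL) {
  if (length(tiles) == 0L) stop("no tiles to split", call. = FALSE)
  fr <- c(fractions@train, fractions@validation, fractions@test)
  part <- integer(length(tiles))
  if (!is.null(groupIds)) {
    if (length(groupIds) != length(tiles))
      stop("groupIds must match tiles in length", call. = FALSE)
    groups <- unique(groupIds)
    sizes <- .largestRemainder(length(groups), fr)
    ord <- .withSeed(seed, sample(groups))
    gPart <- rep.int(1:3, sizes)
    part <- gPart[match(groupIds, ord)]
  } else {
    labels <- vapply(tiles, .tileLabel, "")
    seeds <- .deriveSeeds(seed, length(unique(labels)))
    for (i in seq_along(unique(labels))) {
      idx <- which(labels == unique(labels)[i])
      sizes <- .largestRemainder(length(idx), fr)
      shuffled <- .withSeed(seeds[i], sample(idx))
      part[shuffled] <- rep.int(1:3, sizes)
    }
  }
  new("DatasetSplit", train = tiles[part == 1L],
      validation = tiles[part == 2L], test = tiles[part == 3L])
}

#' Per-class tile counts of a split
#'
#' @param split a [DatasetSplit-class].
#' @return Integer matrix, classes x (train, validation, test).
#' @export
splitClassCounts <- function(split) {
  lv <- gradeLevels()
  cnt <- function(tiles)
    table(factor(vapply(tiles, .tileLabel, ""), levels = lv))
  out <- cbind(train = cnt(split@train), validation = cnt(split@validation),
               test = cnt(split@test))
  out[rowSums(out) > 0, , drop = FALSE]
}

## 90-degree counter-clockwise rotation of a matrix.
.rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

#' Deterministic tile transform (rotation, flips, brightness)
#'
#' The augmentation primitive with explicit arguments; [augmentTile()]
#' draws the arguments from a seed.
#'
#' @param pixels \code{s x s x 3} raster.
#' @param rotate rotation in degrees, a multiple of 90.
#' @param flipH,flipV horizontal / vertical mirroring.
#' @param brightness multiplicative factor; output is clipped to
#'   [0, 255].
#' @return Transformed raster of identical shape.
#' @export
transformTile <- function(pixels, rotate = 0, flipH = FALSE, flipV = FALSE,
                          brightness = 1) {
  if (rotate %% 90 != 0) stop("rotate must be a multiple of 90", call. = FALSE)
  k <- (rotate / 90) %% 4
  out <- pixels
  if (k > 0) {
    d <- dim(out)
    rotated <- out
    for (ch in 1:3) {
      m <- out[, , ch]
      for (i in seq_len(k)) m <- .rot90(m)
      rotated[, , ch] <- m
    }
    out <- rotated
  }
  if (flipH) out <- out[, dim(out)[2]:1, , drop = FALSE]
  if (flipV) out <- out[dim(out)[1]:1, , , drop = FALSE]
  if (brightness != 1) out <- pmin(pmax(out * brightness, 0), 255)
  out
}

## Draw augmentation arguments from the current RNG stream.
.drawAugmentArgs <- function(config) {
  a <- config$augment
  list(rotate = if (isTRUE(a[["rotations"]])) 90 * (sample.int(4L, 1L) - 1L)
                else 0,
       flipH = isTRUE(a[["flips"]]) && stats::runif(1) < 0.5,
       flipV = isTRUE(a[["flips"]]) && stats::runif(1) < 0.5,
       brightness = if (isTRUE(a[["brightness"]]))
                      stats::runif(1, 1 - config$brightnessRange,
                                   1 + config$brightnessRange) else 1)
}

#' Randomly augment a labelled tile
#'
#' Applies a seed-chosen combination of 90-degree rotation, horizontal
#' and vertical flips and multiplicative brightness (the three transforms
#' used when training the grading network). The label is never changed.
#'
#' @param tile a [LabeledTile-class].
#' @param seed RNG seed choosing the transform.
#' @param config a [trainingConfig()] whose \code{augment} switches and
#'   \code{brightnessRange} are honoured.
#' @return An augmented [LabeledTile-class] with the same label.
#' @export
augmentTile <- function(tile, seed = 1L, config = trainingConfig()) {
  args <- .withSeed(seed, .drawAugmentArgs(config))
  new("LabeledTile",
      pixels = transformTile(tile@pixels, args$rotate, args$flipH,
                             args$flipV, args$brightness),
      label = tile@label, seed = tile@seed)
}

## ---- deterministic texture baseline ------------------------------------

## Fixed texture-feature embedding: collagen fraction, tissue fraction,
## mean luminance, edge density, ring score. The ring score measures how
## annular the non-airspace mass is (low radial spread around its
## centroid), which isolates the non-alveolar bronchus/vessel surrogate.
.tileFeatures <- function(pixels, palette) {
  pf <- paletteFractions(pixels, palette)
  lum <- .luminance(array(pixels, dim(pixels)))
  edge <- (mean(abs(diff(lum))) + mean(abs(t(diff(t(lum)))))) / 2
  n <- prod(dim(pixels)[1:2])
  flat <- matrix(pixels, n, 3)
  d <- sapply(1:3, function(k)
    rowSums((flat - matrix(palette[k, ], n, 3, byrow = TRUE))^2))
  dark <- max.col(-d, ties.method = "first") != 1L
  ring <- 0
  if (sum(dark) >= 30) {
    h <- dim(pixels)[1]
    ys <- ((which(dark) - 1) %% h) + 1
    xs <- ((which(dark) - 1) %/% h) + 1
    r <- sqrt((ys - mean(ys))^2 + (xs - mean(xs))^2)
    if (mean(r) > 0) ring <- max(0, 1 - stats::sd(r) / mean(r))
  }
  c(collagen = unname(pf["collagen"]), tissue = unname(pf["tissue"]),
    luminance = mean(lum), edge = edge, ring = ring)
}

#' Deterministic nearest-centroid texture baseline
#'
#' A training-free stand-in for the convolutional classifier: tiles are
#' embedded in a fixed 5-dimensional texture-feature space and classified
#' by nearest class centroid (standardized Euclidean distance). Used as a
#' fast, exactly reproducible oracle in pipeline tests.
#'
#' @param tiles list of [LabeledTile-class] (>= 1 per represented class).
#' @param palette palette for the palette-fraction features.
#' @return A [CentroidClassifier-class].
#' @export
baselineTextureClassifier <- function(tiles,
                                      palette = textureParams()@palette) {
  if (length(tiles) == 0L) stop("no training tiles", call. = FALSE)
  labels <- vapply(tiles, .tileLabel, "")
  feats <- t(vapply(tiles, function(t) .tileFeatures(t@pixels, palette),
                    numeric(5)))
  center <- colMeans(feats)
  ## Diagonal-LDA scaling: pooled within-class sd, so features that are
  ## tight within a class but move across classes dominate the metric.
  ## Degenerate (zero/NA) scales fall back to the global sd, then to 1.
  perClass <- lapply(unique(labels), function(l) {
    f <- feats[labels == l, , drop = FALSE]
    if (nrow(f) > 1) apply(f, 2, stats::var) * (nrow(f) - 1) else NULL
  })
  df <- sum(vapply(unique(labels), function(l)
    max(0L, sum(labels == l) - 1L), integer(1)))
  scale <- if (df > 0) sqrt(Reduce(`+`, Filter(Negate(is.null), perClass)) / df)
           else apply(feats, 2, stats::sd)
  globalSd <- apply(feats, 2, stats::sd)
  bad <- is.na(scale) | scale == 0
  scale[bad] <- globalSd[bad]
  scale[is.na(scale) | scale == 0] <- 1
  z <- sweep(sweep(feats, 2, center), 2, scale, "/")
  present <- sort(unique(labels))
  centroids <- t(vapply(present,
                        function(l) colMeans(z[labels == l, , drop = FALSE]),
                        numeric(5)))
  rownames(centroids) <- present
  new("CentroidClassifier", classes = gradeLevels(),
      metadata = list(architecture = "centroid_texture_baseline",
                      nTrain = length(tiles)),
      centroids = centroids, featureCenter = center, featureScale = scale,
      palette = palette)
}

## Normalise predictTile input to a list of pixel arrays.
.asTileList <- function(tiles) {
  if (is(tiles, "LabeledTile")) return(list(tiles@pixels))
  if (is.array(tiles) && length(dim(tiles)) == 3L) return(list(tiles))
  if (is.list(tiles))
    return(lapply(tiles, function(t) if (is(t, "LabeledTile")) t@pixels else t))
  stop("tiles must be rasters or LabeledTile objects", call. = FALSE)
}

#' @rdname predictTile
#' @export
setMethod("predictTile", "CentroidClassifier", function(model, tiles) {
  px <- .asTileList(tiles)
  feats <- t(vapply(px, function(p) .tileFeatures(p, model@palette),
                    numeric(5)))
  z <- sweep(sweep(feats, 2, model@featureCenter), 2, model@featureScale, "/")
  d2 <- t(apply(z, 1, function(v)
    rowSums(sweep(model@centroids, 2, v)^2)))
  if (nrow(model@centroids) == 1L) d2 <- matrix(d2, ncol = 1L)
  w <- exp(-(d2 - apply(d2, 1, min)) / 2)
  w <- w / rowSums(w)
  probs <- matrix(0, nrow(w), length(model@classes),
                  dimnames = list(NULL, model@classes))
  probs[, rownames(model@centroids)] <- w
  probs
})

#' Predict a grade map over a tile grid
#'
#' Applies the classifier to every tile of the grid. Each tile gets the
#' argmax class of its probability vector; ties resolve to the lower
#' grade (non-alveolar last). Tiles flagged low-tissue by the tiler, and
#' tiles predicted non-alveolar, are marked excluded from scoring.
#'
#' @param model a [ClassifierModel-class].
#' @param grid a [TileGrid-class].
#' @return A [TileGradeMap-class] aligned with the grid.
#' @export
predictGrades <- function(model, grid) {
  if (length(grid@tiles) == 0L) stop("empty tile grid", call. = FALSE)
  probs <- predictTile(model, grid@tiles)
  classes <- classLabels(model)
  labels <- classes[max.col(probs, ties.method = "first")]
  m <- grid@manifest
  nR <- max(m$row) + 1L
  nC <- max(m$col) + 1L
  labMat <- matrix(nonAlveolarLabel(), nR, nC)
  excMat <- matrix(TRUE, nR, nC)
  for (k in seq_len(nrow(m))) {
    labMat[m$row[k] + 1L, m$col[k] + 1L] <- labels[k]
    excMat[m$row[k] + 1L, m$col[k] + 1L] <-
      m$excluded[k] || labels[k] == nonAlveolarLabel()
  }
  new("TileGradeMap", labels = labMat, excluded = excMat, probs = probs,
      tileSize = grid@tileSize, ident = grid@ident)
}

#' Construct a TileGradeMap directly
#'
#' For manual annotations or tests: wraps a label matrix (and optional
#' exclusion flags) into a [TileGradeMap-class]. Non-alveolar tiles are
#' always excluded, whatever \code{excluded} says.
#'
#' @param labels character or numeric matrix of grades /
#'   \code{"non_alveolar"}.
#' @param excluded optional logical matrix of extra exclusions (e.g. low
#'   tissue).
#' @param tileSize tile side in pixels.
#' @param ident section identifier.
#' @return A [TileGradeMap-class].
#' @export
tileGradeMap <- function(labels, excluded = NULL, tileSize = 512L,
                         ident = "section") {
  if (!is.matrix(labels)) labels <- matrix(labels, nrow = 1L)
  labels <- apply(labels, c(1, 2), .normalizeLabel)
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(labels), ncol(labels))
  excluded <- excluded | labels == nonAlveolarLabel()
  new("TileGradeMap", labels = labels, excluded = excluded,
      probs = matrix(numeric(0), 0, 0), tileSize = as.integer(tileSize),
      ident = ident)
}
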