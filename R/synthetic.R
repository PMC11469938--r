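## Procedural synthetic histology: labelled tiles and whole sections with
## known grade maps. The generator is a surrogate for the ordinal fibrosis
## scale, not for real stain physics: a thin-walled alveolar lattice at
## grade 0 whose walls thicken and which accumulates collagen-coloured
## fibrotic masses as the grade rises, reaching near-uniform collagen at
## grade 8. Non-alveolar tiles render a large ring (bronchus/vessel
## surrogate) that is geometrically distinct from every grade.

#' Default parameters of the synthetic tile generator
#'
#' @param palette 3 x 3 RGB matrix with rows \code{airspace},
#'   \code{tissue}, \code{collagen}. The default emulates a trichrome-like
#'   look: near-white airspace, pink tissue, blue collagen.
#' @param wallThickness 9 strictly increasing alveolar-wall thicknesses in
#'   pixels, grades 0..8.
#' @param massFraction 9 strictly increasing target area fractions of
#'   fibrotic (collagen-coloured) masses, grade 0 = 0 and grade 8 = 1.
#' @param noiseSd per-channel Gaussian noise sd in 8-bit counts.
#' @param seed default seed used by generator operations when none is
#'   passed.
#' @return A [TextureParams-class].
#' @export
#' @examples
#' p <- textureParams()
#' p@massFraction
textureParams <- function(palette = NULL,
                          wallThickness = seq(1.2, 4.4, by = 0.4),
                          massFraction = c(0, 0.06, 0.14, 0.24, 0.36,
                                           0.50, 0.64, 0.80, 1.00),
                          noiseSd = 8,
                          seed = 1L) {
  if (is.null(palette)) {
    palette <- rbind(airspace = c(247, 245, 248),
                     tissue = c(196, 120, 160),
                     collagen = c(60, 80, 175))
  }
  new("TextureParams", palette = palette,
      wallThickness = as.numeric(wallThickness),
      massFraction = as.numeric(massFraction),
      noiseSd = noiseSd, seed = as.integer(seed))
}

## Accept 0..8 (numeric or character) and non_alveolar ("NA" alias).
.normalizeLabel <- function(label) {
  if (is.numeric(label)) {
    if (length(label) != 1L || is.na(label) || label != round(label) ||
        label < 0 || label > 8)
      stop("grade must be an integer 0-8 or 'non_alveolar'", call. = FALSE)
    return(as.character(as.integer(label)))
  }
  label <- as.character(label)
  if (label %in% c("NA", "na", "NON_ALVEOLAR")) label <- nonAlveolarLabel()
  if (!label %in% gradeLevels())
    stop("unknown grade label '", label, "'", call. = FALSE)
  label
}

## Pixel class map: 0 airspace, 1 tissue (walls/ring), 2 collagen.
## Must run inside .withSeed().
.renderClassMap <- function(label, size, params) {
  YX <- expand.grid(y = seq_len(size), x = seq_len(size))
  YY <- matrix(YX$y, size, size)
  XX <- matrix(YX$x, size, size)
  cls <- matrix(0L, size, size)
  if (label == nonAlveolarLabel()) {
    cy <- size / 2 + stats::runif(1, -size / 16, size / 16)
    cx <- size / 2 + stats::runif(1, -size / 16, size / 16)
    rOut <- stats::runif(1, 0.32, 0.42) * size
    thick <- stats::runif(1, 0.12, 0.18) * size
    d <- sqrt((YY - cy)^2 + (XX - cx)^2)
    cls[d <= rOut & d >= rOut - thick] <- 1L
    return(cls)
  }
  g <- as.integer(label)
  ## Voronoi-ridge alveolar lattice: walls where the two nearest alveolar
  ## centres are nearly equidistant.
  nCentres <- max(4L, round(1.3 * (size / 12)^2))
  cy <- stats::runif(nCentres, 0.5, size + 0.5)
  cx <- stats::runif(nCentres, 0.5, size + 0.5)
  m1 <- matrix(Inf, size, size)
  m2 <- matrix(Inf, size, size)
  for (j in seq_len(nCentres)) {
    d <- (YY - cy[j])^2 + (XX - cx[j])^2
    closer <- d < m1
    m2 <- pmin(m2, ifelse(closer, m1, d))
    m1 <- pmin(m1, d)
  }
  cls[sqrt(m2) - sqrt(m1) < params@wallThickness[g + 1L]] <- 1L
  ## Fibrotic masses: random disks until the target area is covered.
  target <- params@massFraction[g + 1L]
  if (target >= 0.999) {
    cls[] <- 2L
  } else if (target > 0) {
    covered <- matrix(FALSE, size, size)
    total <- size * size
    for (iter in seq_len(5000L)) {
      if (sum(covered) / total >= target) break
      r <- stats::runif(1, size / 20, size / 12)
      my <- stats::runif(1, 0.5, size + 0.5)
      mx <- stats::runif(1, 0.5, size + 0.5)
      covered <- covered | ((YY - my)^2 + (XX - mx)^2 <= r^2)
    }
    cls[covered] <- 2L
  }
  cls
}

#' Generate one labelled synthetic tile
#'
#' Deterministic in \code{(label, seed, params, tileSize)}: two calls with
#' identical arguments return bit-identical rasters.
#'
#' @param label grade 0-8 (integer or character) or
#'   \code{"non_alveolar"}.
#' @param seed RNG seed; defaults to \code{params@seed}.
#' @param params a [TextureParams-class].
#' @param tileSize tile side in pixels (default 64, the desk-scale
#'   fixture size; any size >= 16 renders).
#' @return A [LabeledTile-class].
#' @export
#' @examples
#' t0 <- generateTile(0, seed = 1)
#' t8 <- generateTile(8, seed = 1)
#' paletteFractions(t0@pixels)["collagen"]
#' paletteFractions(t8@pixels)["collagen"]
generateTile <- function(label, seed = params@seed, params = textureParams(),
                         tileSize = 64L) {
  label <- .normalizeLabel(label)
  tileSize <- as.integer(tileSize)
  if (tileSize < 16L) stop("tileSize must be >= 16", call. = FALSE)
  pixels <- .withSeed(seed, {
    cls <- .renderClassMap(label, tileSize, params)
    base <- array(0, c(tileSize, tileSize, 3L))
    for (ch in 1:3) {
      chan <- params@palette[cls + 1L, ch]
      if (params@noiseSd > 0)
        chan <- chan + stats::rnorm(length(chan), 0, params@noiseSd)
      base[, , ch] <- matrix(chan, tileSize, tileSize)
    }
    pmin(pmax(round(base), 0), 255)
  })
  new("LabeledTile", pixels = pixels, label = label, seed = as.integer(seed))
}

#' Fraction of pixels nearest each palette colour
#'
#' Assigns every pixel to the nearest of the three palette colours
#' (airspace, tissue, collagen) by Euclidean RGB distance and returns the
#' fraction of each — the computable ground-truth texture summary of
#' synthetic tiles.
#'
#' @param pixels \code{h x w x 3} raster.
#' @param palette 3 x 3 palette matrix (default [textureParams()]'s).
#' @return Named numeric vector \code{airspace, tissue, collagen},
#'   summing to 1.
#' @export
paletteFractions <- function(pixels, palette = textureParams()@palette) {
  n <- prod(dim(pixels)[1:2])
  flat <- matrix(pixels, n, 3)
  d <- sapply(1:3, function(k)
    rowSums((flat - matrix(palette[k, ], n, 3, byrow = TRUE))^2))
  idx <- max.col(-d, ties.method = "first")
  out <- tabulate(idx, 3) / n
  names(out) <- c("airspace", "tissue", "collagen")
  out
}

#' Generate a labelled synthetic tile dataset
#'
#' Produces exactly the requested number of tiles per class, each with a
#' distinct seed derived from \code{seed}, in an order shuffled
#' deterministically by \code{seed}.
#'
#' @param counts named vector of per-class tile counts; names are grade
#'   labels (\code{"NA"} is accepted as an alias for non-alveolar).
#' @param seed RNG seed.
#' @param params a [TextureParams-class].
#' @param tileSize tile side in pixels.
#' @return List of [LabeledTile-class].
#' @export
#' @examples
#' tiles <- generateLabeledDataset(c("0" = 3, "8" = 3), seed = 1)
#' table(vapply(tiles, function(t) t@label, ""))
generateLabeledDataset <- function(counts, seed = params@seed,
                                   params = textureParams(), tileSize = 64L) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of per-class tile counts",
         call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  labels <- vapply(names(counts), .normalizeLabel, "")
  expanded <- rep(labels, times = as.integer(counts))
  n <- length(expanded)
  if (n == 0L) return(list())
  seeds <- .deriveSeeds(seed, n + 1L)
  tiles <- lapply(seq_len(n), function(i)
    generateTile(expanded[i], seed = seeds[i], params = params,
                 tileSize = tileSize))
  ord <- .withSeed(seeds[n + 1L], sample.int(n))
  tiles[ord]
}

#' Random grade map over a tile grid
#'
#' Convenience generator of ground-truth grade layouts, optionally from a
#' named profile of grade frequencies.
#'
#' @param rows,cols grid shape.
#' @param seed RNG seed.
#' @param profile one of \code{"uniform"} (all 10 classes equally),
#'   \code{"normal"} (mostly grades 0-1), \code{"bleo_day14"} (fibrotic,
#'   centred on grades 3-6), \code{"severe"} (grades 6-8).
#' @return Character matrix of labels.
#' @export
randomGradeMap <- function(rows, cols, seed = 1L, profile = "uniform") {
  pr <- switch(profile,
    uniform = rep(1, 10),
    normal = c(50, 30, 10, 4, 2, 1, 0, 0, 0, 3),
    bleo_day14 = c(2, 4, 8, 14, 18, 18, 14, 8, 4, 10),
    severe = c(0, 0, 1, 2, 4, 8, 16, 30, 35, 4),
    stop("unknown profile '", profile, "'", call. = FALSE))
  lv <- gradeLevels()
  .withSeed(seed, matrix(sample(lv, rows * cols, replace = TRUE,
                                prob = pr / sum(pr)),
                         nrow = rows, ncol = cols))
}

#' Generate a whole synthetic section from a grade map
#'
#' Assembles a mosaic of generated tiles following the ground-truth grade
#' map, and returns the map's true composite score (mean grade over
#' non-non-alveolar tiles) alongside.
#'
#' @param gradeMap character (or numeric) matrix of labels; see
#'   [randomGradeMap()].
#' @param tileSize tile side in pixels.
#' @param seed RNG seed; per-tile seeds are derived from it.
#' @param params a [TextureParams-class].
#' @param ident identifier for the produced section.
#' @return List with elements \code{section} ([SectionImage-class] of
#'   dimension \code{nrow(gradeMap) * tileSize} by
#'   \code{ncol(gradeMap) * tileSize}), \code{gradeMap} (normalised
#'   character matrix) and \code{trueScore}.
#' @export
#' @examples
#' gm <- matrix(c("0", "8", "non_alveolar", "4"), 2, 2)
#' s <- generateSection(gm, tileSize = 32, seed = 1)
#' s$trueScore  # (0 + 8 + 4) / 3
generateSection <- function(gradeMap, tileSize = 64L, seed = params@seed,
                            params = textureParams(), ident = "synthetic") {
  if (length(gradeMap) == 0L) stop("gradeMap must be non-empty", call. = FALSE)
  if (!is.matrix(gradeMap)) gradeMap <- matrix(gradeMap, nrow = 1L)
  labels <- apply(gradeMap, c(1, 2), .normalizeLabel)
  graded <- labels[labels != nonAlveolarLabel()]
  if (length(graded) == 0L)
    stop("gradeMap contains only non-alveolar tiles; the true score is ",
         "undefined", call. = FALSE)
  trueScore <- mean(as.numeric(graded))
  nR <- nrow(labels); nC <- ncol(labels)
  seeds <- .deriveSeeds(seed, nR * nC)
  px <- array(0, c(nR * tileSize, nC * tileSize, 3L))
  k <- 0L
  for (r in seq_len(nR)) {
    for (cc in seq_len(nC)) {
      k <- k + 1L
      tile <- generateTile(labels[r, cc], seed = seeds[k], params = params,
                           tileSize = tileSize)
      px[(r - 1L) * tileSize + seq_len(tileSize),
         (cc - 1L) * tileSize + seq_len(tileSize), ] <- tile@pixels
    }
  }
  list(section = sectionImage(px, stain = "synthetic", ident = ident),
       gradeMap = labels, trueScore = trueScore)
}
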