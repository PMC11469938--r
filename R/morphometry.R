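## Quantitative %-area staining morphometry and whole-lobule stereology:
## positive-pixel fractions relative to total sectional (tissue) area,
## Archimedes lobule volume from displaced-fluid mass, whole-lobule
## marker volume, and serial-section representativeness summaries.

#' Positive-pixel rule for a stain
#'
#' Real-slide presets are explicit hue/saturation/luminance windows
#' (uncalibrated: the thresholds the original analyses used in commercial
#' software are unpublished); the \code{"synthetic"} profile uses the
#' exact nearest-palette rule of the synthetic generator, so oracles are
#' computable.
#'
#' @param stain one of [stainLabels()].
#' @param hueRange positive hue window in degrees [0, 360) (wrapping
#'   allowed, e.g. \code{c(330, 30)} for reds).
#' @param minSaturation minimum HSV saturation of a positive pixel.
#' @param maxLuminance maximum luminance fraction of a positive pixel.
#' @param palette palette for the synthetic nearest-palette rule.
#' @return List of class \code{"stainProfile"}.
#' @export
stainProfile <- function(stain, hueRange = NULL, minSaturation = NULL,
                         maxLuminance = NULL,
                         palette = textureParams()@palette) {
  stain <- match.arg(stain, stainLabels())
  preset <- switch(stain,
    "PSR" = list(hueRange = c(320, 20), minSaturation = 0.25,
                 maxLuminance = 0.85),
    "MT" = list(hueRange = c(180, 280), minSaturation = 0.15,
                maxLuminance = 0.90),
    "IHC-Col1a1" = ,
    "IHC-Col3" = ,
    "IHC-aSMA" = ,
    "IHC-Gal3" = list(hueRange = c(10, 50), minSaturation = 0.20,
                      maxLuminance = 0.80),
    "synthetic" = list(hueRange = NULL, minSaturation = NULL,
                       maxLuminance = NULL))
  prof <- list(stain = stain,
               mode = if (stain == "synthetic") "palette" else "hsl",
               hueRange = if (is.null(hueRange)) preset$hueRange else hueRange,
               minSaturation = if (is.null(minSaturation))
                 preset$minSaturation else minSaturation,
               maxLuminance = if (is.null(maxLuminance))
                 preset$maxLuminance else maxLuminance,
               palette = palette)
  class(prof) <- "stainProfile"
  prof
}

## Logical matrix of positive pixels under a profile.
.positivePixels <- function(pixels, profile) {
  d <- dim(pixels)
  if (profile$mode == "palette") {
    n <- d[1] * d[2]
    flat <- matrix(pixels, n, 3)
    dist <- sapply(1:3, function(k)
      rowSums((flat - matrix(profile$palette[k, ], n, 3, byrow = TRUE))^2))
    return(matrix(max.col(-dist, ties.method = "first") == 3L, d[1], d[2]))
  }
  hsv <- grDevices::rgb2hsv(t(matrix(pixels, d[1] * d[2], 3)),
                            maxColorValue = 255)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  lum <- c(.luminance(pixels))
  hr <- profile$hueRange
  inHue <- if (hr[1] <= hr[2]) hue >= hr[1] & hue <= hr[2]
           else hue >= hr[1] | hue <= hr[2]
  matrix(inHue & sat >= profile$minSaturation &
           lum <= profile$maxLuminance, d[1], d[2])
}

#' Positive-staining area fraction of a section
#'
#' Positive pixels (per the stain profile) intersected with the tissue
#' mask, as a percentage of the total sectional area. By default the
#' denominator is the tissue area (background glass excluded);
#' \code{denominator = "raster"} switches to the full raster.
#'
#' @param section a [SectionImage-class].
#' @param profile a [stainProfile()].
#' @param mask a [TissueMask-class] congruent with the section; computed
#'   with default thresholds when missing.
#' @param denominator \code{"tissue"} (default) or \code{"raster"}.
#' @return An [AreaFraction-class].
#' @export
positiveAreaFraction <- function(section, profile = stainProfile("synthetic"),
                                 mask = NULL,
                                 denominator = c("tissue", "raster")) {
  denominator <- match.arg(denominator)
  if (is.null(mask)) mask <- tissueMask(section)
  if (!identical(dim(mask@mask), dim(section@pixels)[1:2]))
    stop("mask is not congruent with the section", call. = FALSE)
  pos <- .positivePixels(section@pixels, profile)
  nTissue <- if (denominator == "tissue") sum(mask@mask)
             else length(mask@mask)
  if (nTissue == 0)
    stop("no tissue pixels: the area fraction is undefined", call. = FALSE)
  nPos <- sum(pos & mask@mask)
  new("AreaFraction", percent = 100 * nPos / nTissue,
      nPositive = as.numeric(nPos), nTissue = as.numeric(nTissue),
      ident = section@ident)
}

#' Lung-lobe volume from displaced-fluid mass
#'
#' Archimedes principle: the immersed lobe displaces its volume of
#' fluid, so volume (mL) = displaced mass (g) / fluid density (g/mL).
#'
#' @param massG displaced-fluid mass in grams (> 0).
#' @param densityGPerMl fluid density in g/mL (default 1.0).
#' @return A [LobuleVolume-class]; see also [volumeMm3()] and
#'   [volumeUm3()].
#' @export
#' @examples
#' volumeMl(lobuleVolumeFromDisplacement(0.25))  # 0.25 mL
lobuleVolumeFromDisplacement <- function(massG, densityGPerMl = 1.0) {
  .assertScalarNumber(massG, "massG")
  .assertScalarNumber(densityGPerMl, "densityGPerMl")
  if (massG <= 0) stop("massG must be > 0", call. = FALSE)
  if (densityGPerMl <= 0) stop("densityGPerMl must be > 0", call. = FALSE)
  new("LobuleVolume", volumeMl = massG / densityGPerMl, massG = massG,
      density = densityGPerMl)
}

#' Unit conversions for lobule and marker volumes
#'
#' @param x a [LobuleVolume-class] or [MarkerVolume-class].
#' @return Volume in cubic millimetres / cubic micrometres.
#' @export
volumeMm3 <- function(x) volumeMl(x) * 1e3

#' @rdname volumeMm3
#' @export
volumeUm3 <- function(x) volumeMl(x) * 1e12

#' Whole-lobule marker volume from serial-section %-areas
#'
#' Mean %-area of the marker across serial sections, times the lobule
#' volume: \eqn{V_{marker} = \overline{\%area}/100 \times V_{lobule}}.
#' The single-section estimate (first or designated section) is reported
#' alongside the serial-section mean.
#'
#' @param areaFractions numeric vector of %-areas or list of
#'   [AreaFraction-class] (>= 1).
#' @param volume a [LobuleVolume-class].
#' @param singleIndex which section to report as the single-section
#'   estimate (default 1).
#' @return A [MarkerVolume-class].
#' @export
#' @examples
#' v <- lobuleVolumeFromDisplacement(0.25)
#' volumeMl(wholeLobuleMarkerVolume(10, v))  # 0.025 mL
wholeLobuleMarkerVolume <- function(areaFractions, volume, singleIndex = 1L) {
  pct <- .asPercentVector(areaFractions)
  if (length(pct) == 0L) stop("no area fractions", call. = FALSE)
  if (singleIndex < 1L || singleIndex > length(pct))
    stop("singleIndex out of range", call. = FALSE)
  new("MarkerVolume",
      volumeMl = mean(pct) / 100 * volume@volumeMl,
      singleSectionMl = pct[singleIndex] / 100 * volume@volumeMl,
      meanPercent = mean(pct), lobule = volume)
}

.asPercentVector <- function(areaFractions) {
  if (is.numeric(areaFractions)) return(as.numeric(areaFractions))
  vapply(areaFractions, function(f) {
    if (!is(f, "AreaFraction")) stop("expected AreaFraction objects",
                                     call. = FALSE)
    f@percent
  }, numeric(1))
}

#' Serial-section representativeness summary
#'
#' For the %-areas of one lobule's serial sections (sampled every
#' \code{spacingUm} microns): per-section values, mean, SD, coefficient
#' of variation, and each section's absolute and relative deviation from
#' the lobule mean — the statistic behind asking whether a single section
#' represents the whole lobule.
#'
#' @param fractions numeric %-areas or list of [AreaFraction-class]
#'   (>= 2 sections).
#' @param spacingUm distance between consecutive sections in microns
#'   (default 300; carried as metadata).
#' @return List with \code{perSection} data.frame (\code{section,
#'   percent, deviation, relativeDeviation}), \code{mean}, \code{sd},
#'   \code{cv} and \code{spacingUm}.
#' @export
#' @examples
#' serialSectionSummary(c(8, 12))$perSection$relativeDeviation  # -0.2, 0.2
serialSectionSummary <- function(fractions, spacingUm = 300) {
  pct <- .asPercentVector(fractions)
  if (length(pct) < 2L)
    stop("need >= 2 serial sections", call. = FALSE)
  m <- mean(pct)
  s <- stats::sd(pct)
  list(perSection = data.frame(section = seq_along(pct), percent = pct,
                               deviation = pct - m,
                               relativeDeviation = if (m == 0) rep(0, length(pct))
                                                   else (pct - m) / m),
       mean = m, sd = s, cv = if (m == 0) 0 else s / m,
       spacingUm = spacingUm)
}
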