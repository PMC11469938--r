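## Internal helpers: seeded evaluation, derived seeds, validation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators do not
#' perturb the caller's random stream.
#' @noRd
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive n child seeds from a parent seed
#'
#' Child seeds are drawn from the parent's stream and kept strictly below
#' 2^31 so they remain valid R integer seeds.
#' @noRd
.deriveSeeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  .withSeed(seed, sample.int(2147483646L, n, replace = FALSE))
}

.assertScalarNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single non-missing number", call. = FALSE)
  if (x < min || x > max)
    stop(name, " must be in [", min, ", ", max, "]", call. = FALSE)
  invisible(x)
}

## Round half away from zero (base round() is banker's rounding).
.roundHalfUp <- function(x) floor(x + 0.5)

## Luminance (ITU-R BT.601) of an RGB array or 3-row matrix, on [0, 1].
.luminance <- function(pixels) {
  (0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]) / 255
}

## HSV saturation per pixel of an h x w x 3 array, on [0, 1].
.saturation <- function(pixels) {
  mx <- pmax(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  mn <- pmin(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}
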