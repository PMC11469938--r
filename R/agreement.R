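## Agreement between manual and automated grading: confusion matrices,
## Cohen's kappa (unweighted and ordinal-weighted), Lin's concordance,
## and the manual-vs-automated report.

#' Confusion matrix of reference vs predicted labels
#'
#' @param reference,predicted equal-length label vectors; rows of the
#'   result are reference, columns predicted.
#' @param classes class order; defaults to grades 0-8 (add
#'   \code{nonAlveolarLabel()} to include the non-alveolar class).
#' @return K x K integer matrix with class dimnames.
#' @export
#' @examples
#' confusionMatrix(c(0, 0, 8, 8), c(0, 0, 8, 8), classes = c("0", "8"))
confusionMatrix <- function(reference, predicted,
                            classes = as.character(0:8)) {
  reference <- as.character(reference)
  predicted <- as.character(predicted)
  if (length(reference) != length(predicted))
    stop("reference and predicted must have equal length", call. = FALSE)
  if (length(reference) == 0L) stop("no labels", call. = FALSE)
  bad <- !c(reference, predicted) %in% classes
  if (any(bad))
    stop("labels outside the class order: ",
         paste(unique(c(reference, predicted)[bad]), collapse = ", "),
         call. = FALSE)
  cm <- table(factor(reference, levels = classes),
              factor(predicted, levels = classes))
  matrix(as.integer(cm), nrow = length(classes),
         dimnames = list(reference = classes, predicted = classes))
}

## Disagreement weights over the class-order index for weighted kappa.
.kappaWeights <- function(K, weighting) {
  idx <- seq_len(K)
  d <- abs(outer(idx, idx, "-"))
  switch(weighting,
         none = (d > 0) * 1,
         linear = if (K == 1L) d * 0 else d / (K - 1),
         quadratic = if (K == 1L) d * 0 else (d / (K - 1))^2)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. For
#' the unweighted statistic \eqn{p_o} is the diagonal fraction and
#' \eqn{p_e = \sum_i r_i c_i / N^2} from the marginals. Linear and
#' quadratic variants weight disagreements by their distance on the
#' ordinal scale (positions in the matrix's class order). In the
#' degenerate case \eqn{p_e = 1} the statistic is defined as 1 when
#' \eqn{p_o = 1} and 0 otherwise, and flagged.
#'
#' @param cm square counts matrix from [confusionMatrix()].
#' @param weighting \code{"none"} (default), \code{"linear"} or
#'   \code{"quadratic"}.
#' @return A [KappaResult-class].
#' @export
#' @examples
#' kappaValue(cohenKappa(rbind(c(20, 5), c(10, 15))))  # 0.4
cohenKappa <- function(cm, weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  N <- sum(cm)
  if (N < 1) stop("empty confusion matrix", call. = FALSE)
  d <- .kappaWeights(nrow(cm), weighting)
  w <- 1 - d
  expected <- outer(rowSums(cm), colSums(cm)) / N
  pO <- sum(w * cm) / N
  pE <- sum(w * expected) / N
  degenerate <- abs(1 - pE) < 1e-15
  kappa <- if (degenerate) as.numeric(abs(1 - pO) < 1e-15)
           else (pO - pE) / (1 - pE)
  new("KappaResult", kappa = kappa, pO = min(pO, 1), pE = min(pE, 1),
      weighting = weighting, N = N, degenerate = degenerate)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two continuous measurements around the identity line:
#' \eqn{2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}. Reported for
#' unrounded section scores alongside the discretised kappa.
#'
#' @param x,y numeric vectors of paired measurements.
#' @return The concordance coefficient.
#' @export
linConcordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("need >= 2 paired measurements", call. = FALSE)
  n <- length(x)
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

#' Manual-vs-automated agreement report
#'
#' At \code{level = "tile"}, joins the two tables on
#' \code{ident + row + col} and reports the tile-label confusion matrix
#' with unweighted, linear and quadratic kappa side by side. At
#' \code{level = "section"}, joins on \code{ident}, rounds the composite
#' scores half-up to integer grades for the kappa, and additionally
#' reports Lin's concordance on the unrounded scores. Unmatched rows are
#' dropped with a warning and counted in the report.
#'
#' @param manual,automated data.frames; tile level needs columns
#'   \code{ident}, \code{row}, \code{col}, \code{label}; section level
#'   needs \code{ident}, \code{score}.
#' @param level \code{"tile"} or \code{"section"}.
#' @param includeNonAlveolar include the non-alveolar class as an 11th
#'   agreement class (default \code{FALSE}: non-alveolar tiles are
#'   excluded, as they are from scoring).
#' @return List of class \code{"agreementReport"}: \code{level},
#'   \code{n}, \code{nDropped}, \code{confusion}, \code{kappa} (list of
#'   [KappaResult-class] by weighting) and, at section level,
#'   \code{concordance}.
#' @export
agreementReport <- function(manual, automated,
                            level = c("tile", "section"),
                            includeNonAlveolar = FALSE) {
  level <- match.arg(level)
  keys <- if (level == "tile") c("ident", "row", "col") else "ident"
  for (k in keys) {
    if (!k %in% names(manual) || !k %in% names(automated))
      stop("both tables need column '", k, "'", call. = FALSE)
  }
  merged <- merge(manual, automated, by = keys,
                  suffixes = c(".manual", ".auto"))
  nDropped <- (nrow(manual) - nrow(merged)) + (nrow(automated) - nrow(merged))
  if (nrow(merged) == 0L)
    stop("no matched idents between the two tables", call. = FALSE)
  if (nDropped > 0)
    warning(nDropped, " unmatched rows dropped from the agreement report")
  if (level == "tile") {
    ref <- as.character(merged$label.manual)
    prd <- as.character(merged$label.auto)
    classes <- as.character(0:8)
    if (includeNonAlveolar) classes <- c(classes, nonAlveolarLabel())
    keep <- ref %in% classes & prd %in% classes
    ref <- ref[keep]; prd <- prd[keep]
    cm <- confusionMatrix(ref, prd, classes)
    concordance <- NULL
  } else {
    x <- merged$score.manual
    y <- merged$score.auto
    ref <- as.character(pmin(pmax(.roundHalfUp(x), 0), 8))
    prd <- as.character(pmin(pmax(.roundHalfUp(y), 0), 8))
    cm <- confusionMatrix(ref, prd, as.character(0:8))
    concordance <- if (length(x) >= 2) linConcordance(x, y) else NULL
  }
  kap <- lapply(c(none = "none", linear = "linear",
                  quadratic = "quadratic"),
                function(wg) cohenKappa(cm, wg))
  out <- list(level = level, n = length(ref), nDropped = nDropped,
              confusion = cm, kappa = kap, concordance = concordance)
  class(out) <- "agreementReport"
  out
}

#' @export
print.agreementReport <- function(x, ...) {
  cat("Agreement report (", x$level, " level, N = ", x$n, ")\n", sep = "")
  if (x$nDropped > 0) cat("  unmatched rows dropped:", x$nDropped, "\n")
  for (nm in names(x$kappa))
    cat(sprintf("  kappa (%s): %.4f\n", nm, kappaValue(x$kappa[[nm]])))
  if (!is.null(x$concordance))
    cat(sprintf("  Lin's concordance (unrounded): %.4f\n", x$concordance))
  invisible(x)
}

#' Write an agreement report as JSON
#'
#' @param report an [agreementReport()] result.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeAgreementJSON <- function(report, path) {
  k <- report$kappa$none
  jsonlite::write_json(
    list(level = report$level, N = report$n, nDropped = report$nDropped,
         kappa = kappaValue(k), p_o = k@pO, p_e = k@pE,
         weighting = k@weighting,
         kappa_linear = kappaValue(report$kappa$linear),
         kappa_quadratic = kappaValue(report$kappa$quadratic),
         concordance = report$concordance,
         classes = rownames(report$confusion),
         confusion = unname(apply(report$confusion, 1, as.list))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
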