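## Shared fixture builders. Everything is generated in code at test time;
## no binary fixtures are stored.

## Deterministic random raster on [0, 255].
randomRaster <- function(h, w, seed = 1) {
  set.seed(seed)
  array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)), c(h, w, 3))
}

## A balanced labelled corpus: `n` tiles for each requested class.
balancedCorpus <- function(n, classes = gradeLevels(), seed = 1,
                           params = textureParams(), tileSize = 64L) {
  counts <- stats::setNames(rep(n, length(classes)), classes)
  generateLabeledDataset(counts, seed = seed, params = params,
                         tileSize = tileSize)
}

tileLabelsOf <- function(tiles) vapply(tiles, function(t) t@label, "")

## Argmax labels from a classifier on a list of tiles.
predictedLabels <- function(model, tiles) {
  probs <- predictTile(model, tiles)
  classLabels(model)[max.col(probs, ties.method = "first")]
}

## Brute-force composite score: plain mean over the per-tile grade list.
bruteForceScore <- function(labels, excluded) {
  g <- suppressWarnings(as.numeric(labels[!excluded]))
  mean(g[!is.na(g)])
}

## Brute-force Cohen's kappa by explicit double loops.
bruteForceKappa <- function(cm) {
  K <- nrow(cm)
  N <- sum(cm)
  pO <- 0
  for (i in seq_len(K)) pO <- pO + cm[i, i] / N
  pE <- 0
  for (i in seq_len(K)) {
    ri <- 0; ci <- 0
    for (j in seq_len(K)) {
      ri <- ri + cm[i, j]
      ci <- ci + cm[j, i]
    }
    pE <- pE + (ri * ci) / N^2
  }
  (pO - pE) / (1 - pE)
}
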