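## The reference small convolutional network, implemented in base R.
## Three conv(3x3, same padding)/ReLU/max-pool(2x2) blocks with 8, 16 and
## 32 filters on inputs resized to 32 x 32, a 64-unit dense ReLU layer and
## a 10-way softmax head; trained with Adam on softmax cross-entropy.
## Convolutions are evaluated as im2col gathers followed by one matrix
## multiplication per layer, which keeps 1-CPU training of the desk-scale
## corpora within minutes.
##
## Feature maps are stored as (N*H*W) x C matrices with row index
## (n-1)*H*W + (x-1)*H + y, i.e. images stacked over R's column-major
## spatial flattening.

.convFilters <- c(8L, 16L, 32L)

## Padded-neighbourhood indices for a 3x3 same convolution on H x W.
.convGeom <- function(H, W) {
  pH <- H + 2L
  pos <- expand.grid(y = seq_len(H), x = seq_len(W))
  idx9 <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    idx9[, k] <- (pos$x + 1L + dx - 1L) * pH + (pos$y + 1L + dy)
  }
  list(idx9 = idx9, pH = pH, pW = W + 2L)
}

## 2x2/stride-2 max-pool input indices for each output position.
.poolGeom <- function(H, W) {
  Ho <- H %/% 2L
  pos <- expand.grid(y = seq_len(Ho), x = seq_len(W %/% 2L))
  cbind((2L * pos$x - 2L) * H + (2L * pos$y - 1L),
        (2L * pos$x - 2L) * H + (2L * pos$y),
        (2L * pos$x - 1L) * H + (2L * pos$y - 1L),
        (2L * pos$x - 1L) * H + (2L * pos$y))
}

## Replicate per-image indices across a batch of N images.
.batchIdx <- function(idx, strideIn, N) {
  out <- matrix(0L, nrow(idx) * N, ncol(idx))
  for (k in seq_len(ncol(idx)))
    out[, k] <- as.vector(outer(idx[, k], (seq_len(N) - 1L) * strideIn, "+"))
  out
}

.padBatch <- function(F, H, W, N, C, pH, pW) {
  Pa <- array(0, c(pH, pW, N, C))
  Pa[2:(H + 1L), 2:(W + 1L), , ] <- array(F, c(H, W, N, C))
  matrix(Pa, pH * pW * N, C)
}

.softmaxRows <- function(z) {
  z <- exp(z - apply(z, 1, max))
  z / rowSums(z)
}

## He-normal initialisation of all layers, seeded.
.cnnInit <- function(inputSize, nClasses, seed) {
  .withSeed(seed, {
    w <- list()
    cIn <- 3L
    for (i in seq_along(.convFilters)) {
      cOut <- .convFilters[i]
      fanIn <- 9L * cIn
      w[[paste0("W", i)]] <- matrix(stats::rnorm(fanIn * cOut, 0,
                                                 sqrt(2 / fanIn)),
                                    fanIn, cOut)
      w[[paste0("b", i)]] <- numeric(cOut)
      cIn <- cOut
    }
    s <- inputSize %/% 8L
    flat <- s * s * .convFilters[3]
    w$W4 <- matrix(stats::rnorm(flat * 64L, 0, sqrt(2 / flat)), flat, 64L)
    w$b4 <- numeric(64L)
    w$W5 <- matrix(stats::rnorm(64L * nClasses, 0, sqrt(2 / 64)), 64L,
                   nClasses)
    w$b5 <- numeric(nClasses)
    w
  })
}

## Forward pass on a scaled batch array A (S x S x 3 x N).
## With cache = TRUE returns the intermediates needed for backprop.
.cnnForward <- function(w, A, cache = FALSE) {
  d <- dim(A)
  S <- d[1]; N <- d[4]
  F <- matrix(aperm(A, c(1, 2, 4, 3)), S * S * N, 3L)
  H <- S; W <- S; C <- 3L
  blocks <- vector("list", 3L)
  for (i in 1:3) {
    cg <- .convGeom(H, W)
    P <- .padBatch(F, H, W, N, C, cg$pH, cg$pW)
    idxB <- .batchIdx(cg$idx9, cg$pH * cg$pW, N)
    Cout <- .convFilters[i]
    Xcol <- matrix(0, H * W * N, 9L * C)
    for (k in 1:9)
      Xcol[, (seq_len(C) - 1L) * 9L + k] <- P[idxB[, k], , drop = FALSE]
    Z <- Xcol %*% w[[paste0("W", i)]]
    Z <- sweep(Z, 2, w[[paste0("b", i)]], "+")
    R <- Z * (Z > 0)
    pg <- .poolGeom(H, W)
    pIdxB <- .batchIdx(pg, H * W, N)
    G <- R[pIdxB[, 1], , drop = FALSE]
    amax <- matrix(1L, nrow(G), ncol(G))
    for (k in 2:4) {
      Gk <- R[pIdxB[, k], , drop = FALSE]
      upd <- Gk > G
      amax[upd] <- k
      G[upd] <- Gk[upd]
    }
    if (cache)
      blocks[[i]] <- list(Xcol = Xcol, Z = Z, amax = amax, pIdxB = pIdxB,
                          idxB = idxB, H = H, W = W, C = C,
                          pH = cg$pH, pW = cg$pW)
    F <- G
    H <- H %/% 2L; W <- W %/% 2L; C <- Cout
  }
  flat <- H * W * C
  X4 <- t(matrix(aperm(array(F, c(H * W, N, C)), c(1, 3, 2)), flat, N))
  Z4 <- sweep(X4 %*% w$W4, 2, w$b4, "+")
  R4 <- Z4 * (Z4 > 0)
  logits <- sweep(R4 %*% w$W5, 2, w$b5, "+")
  probs <- .softmaxRows(logits)
  if (!cache) return(probs)
  list(probs = probs, blocks = blocks, X4 = X4, Z4 = Z4, R4 = R4,
       spatial = c(H, W, C), N = N)
}

## Backward pass; returns gradients named like the weights.
.cnnBackward <- function(w, fw, yIdx) {
  N <- fw$N
  dL <- fw$probs
  dL[cbind(seq_len(N), yIdx)] <- dL[cbind(seq_len(N), yIdx)] - 1
  dL <- dL / N
  g <- list()
  g$W5 <- t(fw$R4) %*% dL
  g$b5 <- colSums(dL)
  dR4 <- dL %*% t(w$W5)
  dZ4 <- dR4 * (fw$Z4 > 0)
  g$W4 <- t(fw$X4) %*% dZ4
  g$b4 <- colSums(dZ4)
  dX4 <- dZ4 %*% t(w$W4)
  H <- fw$spatial[1]; W <- fw$spatial[2]; C <- fw$spatial[3]
  dF <- matrix(aperm(array(t(dX4), c(H * W, C, N)), c(1, 3, 2)),
               H * W * N, C)
  for (i in 3:1) {
    bl <- fw$blocks[[i]]
    dR <- matrix(0, bl$H * bl$W * N, ncol(dF))
    for (ch in seq_len(ncol(dF))) {
      rows <- bl$pIdxB[cbind(seq_len(nrow(bl$pIdxB)), bl$amax[, ch])]
      dR[cbind(rows, ch)] <- dF[, ch]
    }
    dZ <- dR * (bl$Z > 0)
    g[[paste0("W", i)]] <- t(bl$Xcol) %*% dZ
    g[[paste0("b", i)]] <- colSums(dZ)
    if (i > 1L) {
      dXcol <- dZ %*% t(w[[paste0("W", i)]])
      dP <- matrix(0, bl$pH * bl$pW * N, bl$C)
      for (k in 1:9) {
        cols <- (seq_len(bl$C) - 1L) * 9L + k
        dP[bl$idxB[, k], ] <- dP[bl$idxB[, k], , drop = FALSE] +
          dXcol[, cols, drop = FALSE]
      }
      dPa <- array(dP, c(bl$pH, bl$pW, N, bl$C))
      dF <- matrix(dPa[2:(bl$H + 1L), 2:(bl$W + 1L), , , drop = FALSE],
                   bl$H * bl$W * N, bl$C)
    }
  }
  g
}

.adamStep <- function(w, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

## Resize tiles to the network input size (still on the 0..255 scale).
.prepTiles <- function(tiles, inputSize) {
  lapply(.asTileList(tiles), function(px) {
    d <- dim(px)
    if (d[1] != inputSize || d[2] != inputSize)
      px <- .resizeArea(px, inputSize, inputSize)
    px
  })
}

.stackBatch <- function(pxList) {
  S <- dim(pxList[[1]])[1]
  A <- array(0, c(S, S, 3L, length(pxList)))
  for (i in seq_along(pxList)) A[, , , i] <- pxList[[i]] / 255 - 0.5
  A
}

.cnnPredictProbs <- function(model, tiles, batch = 128L) {
  px <- .prepTiles(tiles, model@inputSize)
  n <- length(px)
  out <- matrix(0, n, length(model@classes),
                dimnames = list(NULL, model@classes))
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx, ] <- .cnnForward(model@weights, .stackBatch(px[idx]))
  }
  out
}

#' @rdname predictTile
#' @export
setMethod("predictTile", "SmallCNNClassifier", function(model, tiles) {
  .cnnPredictProbs(model, tiles)
})

#' Train the tile-grading classifier
#'
#' Runs exactly \code{config$epochs} epochs of Adam on softmax
#' cross-entropy over the training partition, with seed-driven shuffling
#' and rotation/flip/brightness augmentation, evaluating validation
#' accuracy after every epoch. The returned model carries the weights of
#' the best-validation epoch and the full per-epoch accuracy trace. Fully
#' deterministic for a fixed seed, data and config.
#'
#' @param split a [DatasetSplit-class] with non-empty train and
#'   validation partitions. Balancing is the caller's step (see
#'   [balanceByResampling()] and [trainGradingPipeline()]).
#' @param config a [trainingConfig()].
#' @return A [SmallCNNClassifier-class].
#' @export
trainClassifier <- function(split, config = trainingConfig()) {
  if (config$architecture != "reference_small_cnn")
    stop("architecture '", config$architecture, "' needs a deep-learning ",
         "backend that is not available; use 'reference_small_cnn'",
         call. = FALSE)
  if (length(split@train) == 0L) stop("empty training set", call. = FALSE)
  if (length(split@validation) == 0L)
    stop("empty validation set", call. = FALSE)
  classes <- config$classes
  S <- config$inputSize
  trainPx <- .prepTiles(split@train, S)
  valPx <- .prepTiles(split@validation, S)
  yTrain <- match(vapply(split@train, .tileLabel, ""), classes)
  yVal <- match(vapply(split@validation, .tileLabel, ""), classes)
  seeds <- .deriveSeeds(config$seed, 1L + 2L * config$epochs)
  w <- .cnnInit(S, length(classes), seeds[1])
  state <- list(m = lapply(w, function(x) x * 0),
                v = lapply(w, function(x) x * 0))
  nTrain <- length(trainPx)
  trace <- numeric(config$epochs)
  best <- w
  bestAcc <- -1
  t <- 0L
  valA <- .stackBatch(valPx)
  for (epoch in seq_len(config$epochs)) {
    ord <- .withSeed(seeds[2L * epoch], sample.int(nTrain))
    augSeeds <- .deriveSeeds(seeds[2L * epoch + 1L], nTrain)
    for (start in seq(1L, nTrain, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, nTrain)]
      bpx <- lapply(seq_along(idx), function(i) {
        args <- .withSeed(augSeeds[idx[i]], .drawAugmentArgs(config))
        transformTile(trainPx[[idx[i]]], args$rotate, args$flipH,
                      args$flipV, args$brightness)
      })
      fw <- .cnnForward(w, .stackBatch(bpx), cache = TRUE)
      g <- .cnnBackward(w, fw, yTrain[idx])
      t <- t + 1L
      upd <- .adamStep(w, g, state, config$learningRate, t)
      w <- upd$w
      state <- upd$state
    }
    probs <- .cnnForward(w, valA)
    acc <- mean(max.col(probs, ties.method = "first") == yVal)
    trace[epoch] <- acc
    if (acc > bestAcc) {
      bestAcc <- acc
      best <- w
    }
  }
  new("SmallCNNClassifier", classes = classes,
      metadata = list(architecture = config$architecture,
                      seed = config$seed, epochs = config$epochs,
                      batchSize = config$batchSize,
                      learningRate = config$learningRate,
                      bestEpoch = which.max(trace)),
      weights = best, inputSize = S, trace = trace)
}

#' Split, balance and train in one call
#'
#' The standard assembly order: stratified 75/20/5 split of the labelled
#' tiles, oversampling of the training partition to balance the classes,
#' then training. Splitting precedes balancing so that duplicated tiles
#' can never span two partitions.
#'
#' @param tiles list of [LabeledTile-class].
#' @param fractions a [SplitFractions-class].
#' @param config a [trainingConfig()].
#' @return List with the trained \code{model} and the \code{split} used.
#' @export
trainGradingPipeline <- function(tiles, fractions = splitFractions(),
                                 config = trainingConfig()) {
  seeds <- .deriveSeeds(config$seed, 2L)
  split <- stratifiedSplit(tiles, fractions, seed = seeds[1])
  balanced <- new("DatasetSplit",
                  train = balanceByResampling(split@train, seed = seeds[2]),
                  validation = split@validation, test = split@test)
  list(model = trainClassifier(balanced, config), split = split)
}

#' Write / read a trained model directory
#'
#' The artifact is a directory holding a JSON metadata file and the
#' weights as flat text matrices, so it survives text-only storage.
#'
#' @param model a [SmallCNNClassifier-class].
#' @param dir target directory (created if needed).
#' @return \code{dir} (write) or the model (read).
#' @export
writeModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(model@metadata,
            list(classes = model@classes, inputSize = model@inputSize,
                 trace = model@trace,
                 shapes = lapply(model@weights, function(x)
                   if (is.matrix(x)) dim(x) else length(x))))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "weights.txt"), "w")
  on.exit(close(con))
  for (nm in names(model@weights))
    writeLines(c(nm, paste(format(c(model@weights[[nm]]), digits = 17),
                           collapse = " ")), con)
  invisible(dir)
}

#' @rdname writeModel
#' @export
readModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  lines <- readLines(file.path(dir, "weights.txt"))
  w <- list()
  for (i in seq(1, length(lines), by = 2)) {
    nm <- lines[i]
    vals <- as.numeric(strsplit(trimws(lines[i + 1]), "\\s+")[[1]])
    shape <- unlist(meta$shapes[[nm]])
    w[[nm]] <- if (length(shape) == 2) matrix(vals, shape[1], shape[2])
               else vals
  }
  new("SmallCNNClassifier", classes = meta$classes,
      metadata = list(architecture = meta$architecture, seed = meta$seed,
                      epochs = meta$epochs, bestEpoch = meta$bestEpoch),
      weights = w, inputSize = as.integer(meta$inputSize),
      trace = as.numeric(meta$trace))
}
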