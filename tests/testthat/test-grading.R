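test_that("class balancing oversamples to the majority with real duplicates", {
  tiles <- c(balancedCorpus(10, classes = "0", seed = 1),
             balancedCorpus(2, classes = "4", seed = 2))
  out <- balanceByResampling(tiles, seed = 5)
  counts <- table(tileLabelsOf(out))
  expect_equal(unname(counts[c("0", "4")]), c(10L, 10L), ignore_attr = TRUE)
  ## every added grade-4 tile is bit-identical to one of the two originals
  originals <- lapply(tiles[11:12], function(t) t@pixels)
  added <- out[tileLabelsOf(out) == "4"]
  for (t in added)
    expect_true(any(vapply(originals, identical, TRUE, y = t@pixels)))
  ## already balanced input comes back as the identical multiset
  bal <- tiles[1:4]
  expect_identical(balanceByResampling(bal, seed = 1), bal)
  expect_error(balanceByResampling(list(), seed = 1), "balance")
})

test_that("stratified split apportions 75/20/5 by largest remainder", {
  one <- generateTile(3, seed = 1)
  corpus <- function(n) rep(list(one), n)
  sizes <- function(n) {
    sp <- stratifiedSplit(corpus(n), seed = 2)
    c(length(sp@train), length(sp@validation), length(sp@test))
  }
  expect_equal(sizes(100), c(75L, 20L, 5L))
  expect_equal(sizes(20), c(15L, 4L, 1L))
  ## a single tile goes to the largest fraction
  expect_equal(sizes(1), c(1L, 0L, 0L))
  expect_error(stratifiedSplit(list(), seed = 1), "split")
  expect_error(splitFractions(0.8, 0.3, 0.05), "sum")
})

test_that("splits are disjoint, exhaustive and within one tile per class", {
  tiles <- c(balancedCorpus(13, classes = c("0", "4"), seed = 7),
             balancedCorpus(29, classes = "8", seed = 8))
  fr <- splitFractions()
  sp <- stratifiedSplit(tiles, fr, seed = 3)
  all3 <- c(sp@train, sp@validation, sp@test)
  expect_length(all3, length(tiles))
  ## per-class apportionment error < 1 tile per split
  fracs <- c(fr@train, fr@validation, fr@test)
  for (cl in c("0", "4", "8")) {
    n <- sum(tileLabelsOf(tiles) == cl)
    got <- c(sum(tileLabelsOf(sp@train) == cl),
             sum(tileLabelsOf(sp@validation) == cl),
             sum(tileLabelsOf(sp@test) == cl))
    expect_true(all(abs(got - n * fracs) < 1))
  }
  ## disjointness via per-tile generation seeds (unique by construction)
  seeds <- vapply(all3, function(t) t@seed, 1L)
  expect_length(unique(seeds), length(tiles))
})

test_that("group-aware splitting keeps whole sections together", {
  tiles <- balancedCorpus(4, classes = c("0", "8"), seed = 11)
  groups <- rep(paste0("sec", 1:4), each = 2)
  sp <- stratifiedSplit(tiles, seed = 5, groupIds = groups)
  seedToGroup <- setNames(groups, vapply(tiles, function(t) t@seed, 1L))
  for (part in list(sp@train, sp@validation, sp@test)) {
    gs <- unique(seedToGroup[as.character(vapply(part, function(t) t@seed,
                                                 1L))])
    ## no group may appear in another partition
    others <- setdiff(unlist(lapply(list(sp@train, sp@validation, sp@test),
      function(p) seedToGroup[as.character(vapply(p, function(t) t@seed,
                                                  1L))])), gs)
    expect_length(intersect(gs, others), 0L)
  }
})

test_that("augmentation preserves labels, shape and group structure", {
  tile <- generateTile(5, seed = 9)
  ## explicit identity transform
  expect_identical(transformTile(tile@pixels, 0, FALSE, FALSE, 1),
                   tile@pixels)
  ## 180-degree rotation is an involution
  once <- transformTile(tile@pixels, 180)
  expect_identical(transformTile(once, 180), tile@pixels)
  ## label and raster shape are invariant
  aug <- augmentTile(tile, seed = 3)
  expect_equal(aug@label, tile@label)
  expect_equal(dim(aug@pixels), dim(tile@pixels))
  ## the dihedral subset (rotations x flips) has exactly 8 elements and
  ## is closed under a further rotation
  px <- randomRaster(16, 16, seed = 2)
  d8 <- list()
  for (r in c(0, 90, 180, 270)) for (f in c(FALSE, TRUE))
    d8 <- c(d8, list(transformTile(px, r, flipH = f)))
  expect_length(unique(d8), 8L)
  for (el in d8)
    expect_true(any(vapply(d8, identical, TRUE, y = transformTile(el, 90))))
  ## brightness clips to the valid range
  bright <- transformTile(array(200, c(4, 4, 3)), brightness = 1.5)
  expect_true(all(bright == 255))
})

test_that("the texture baseline is deterministic and self-consistent", {
  tiles <- balancedCorpus(5, classes = c("0", "8"), seed = 13)
  model <- baselineTextureClassifier(tiles)
  ## perfect on its own well-separated training classes
  expect_equal(mean(predictedLabels(model, tiles) == tileLabelsOf(tiles)), 1)
  ## probability rows sum to 1
  probs <- predictTile(model, tiles)
  expect_equal(rowSums(probs), rep(1, length(tiles)))
  expect_true(all(probs >= 0))
  ## single-class training always predicts that class
  mono <- baselineTextureClassifier(balancedCorpus(3, classes = "2",
                                                   seed = 14))
  expect_true(all(predictedLabels(mono, tiles) == "2"))
  expect_error(baselineTextureClassifier(list()), "training")
})

test_that("CNN training is seeded, traced and reproducible", {
  tiles <- balancedCorpus(12, classes = c("0", "4", "8"), seed = 17)
  cfg <- trainingConfig(epochs = 3, seed = 5)
  sp <- stratifiedSplit(tiles, seed = 1)
  m1 <- trainClassifier(sp, cfg)
  expect_length(accuracyTrace(m1), 3L)
  ## identical seed and data give bit-identical predictions
  m2 <- trainClassifier(sp, cfg)
  probe <- generateTile(4, seed = 999)
  expect_identical(predictTile(m1, probe), predictTile(m2, probe))
  ## probabilities normalise
  expect_equal(rowSums(predictTile(m1, tiles[1:5])), rep(1, 5),
               tolerance = 1e-6)
  expect_error(trainClassifier(new("DatasetSplit", train = list(),
                                   validation = sp@validation, test = list()),
                               cfg), "training")
  expect_error(trainingConfig(epochs = 0), "epochs")
  expect_error(trainClassifier(sp, trainingConfig(architecture =
                                                    "inception_v3")),
               "backend")
})

test_that("a separable 2-class corpus is learned nearly perfectly", {
  tiles <- balancedCorpus(50, classes = c("0", "8"), seed = 7)
  res <- trainGradingPipeline(tiles, config = trainingConfig(epochs = 5,
                                                             seed = 7))
  held <- c(res$split@validation, res$split@test)
  acc <- mean(predictedLabels(res$model, held) == tileLabelsOf(held))
  expect_gte(acc, 0.95)
})

test_that("predictGrades fills the grid and applies both exclusion rules", {
  ## a 1x3 mosaic: grade 0, grade 8, and a glass (background) tile
  px <- array(255, c(64, 192, 3))
  px[, 1:64, ] <- generateTile(0, seed = 1)@pixels
  px[, 65:128, ] <- generateTile(8, seed = 2)@pixels
  grid <- tileSection(sectionImage(px, ident = "s"), tileSize = 64)
  model <- baselineTextureClassifier(balancedCorpus(4, seed = 19))
  map <- predictGrades(model, grid)
  expect_equal(dim(tileLabels(map)), c(1L, 3L))
  ## the glass tile is excluded regardless of its prediction
  expect_true(excludedTiles(map)[1, 3])
  expect_equal(tileLabels(map)[1, 1:2], c("0", "8"))
  ## a predicted non-alveolar tile is excluded
  naPx <- array(255, c(64, 64, 3))
  naPx[, , ] <- generateTile("non_alveolar", seed = 3)@pixels
  gridNA <- tileSection(sectionImage(naPx), tileSize = 64)
  mapNA <- predictGrades(model, gridNA)
  if (tileLabels(mapNA)[1, 1] == nonAlveolarLabel())
    expect_true(excludedTiles(mapNA)[1, 1])
})

test_that("model artifacts round-trip through the text format", {
  tiles <- balancedCorpus(8, classes = c("0", "8"), seed = 23)
  sp <- stratifiedSplit(tiles, seed = 1)
  m <- trainClassifier(sp, trainingConfig(epochs = 2, seed = 2))
  dir <- withr::local_tempdir()
  writeModel(m, dir)
  m2 <- readModel(dir)
  probe <- generateTile(8, seed = 50)
  expect_equal(predictTile(m, probe), predictTile(m2, probe),
               tolerance = 1e-12)
})
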