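test_that("loadSection reads PNG and TIFF rasters faithfully", {
  dir <- withr::local_tempdir()
  ## identity read of a white PNG
  white <- file.path(dir, "white.png")
  png::writePNG(array(1, c(64, 64, 3)), white)
  s <- loadSection(white)
  expect_equal(dim(sectionPixels(s)), c(64L, 64L, 3L))
  expect_true(all(sectionPixels(s) == 255))

  ## grayscale inputs are replicated to three channels
  gray <- file.path(dir, "gray.png")
  png::writePNG(matrix(7 / 255, 10, 10), gray)
  g <- loadSection(gray)
  expect_equal(dim(sectionPixels(g)), c(10L, 10L, 3L))
  expect_true(all(sectionPixels(g) == 7))

  ## TIFF round trip is bit-exact, both via writer and reader
  px <- randomRaster(21, 17, seed = 4)
  tif <- file.path(dir, "x.tif")
  writeSection(sectionImage(px, ident = "x"), tif)
  expect_identical(sectionPixels(loadSection(tif)), px * 1)

  ## PNG round trip is bit-exact
  pngf <- file.path(dir, "x.png")
  writeSection(sectionImage(px), pngf)
  expect_identical(sectionPixels(loadSection(pngf)), px * 1)
})

test_that("unreadable or truncated files raise I/O errors, not objects", {
  dir <- withr::local_tempdir()
  expect_error(loadSection(file.path(dir, "missing.png")), "no such file")
  junk <- file.path(dir, "junk.png")
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 1, 2, 3)), junk)
  expect_error(loadSection(junk), "PNG")
  trunc <- file.path(dir, "trunc.tif")
  writeBin(charToRaw("II"), trunc)
  expect_error(loadSection(trunc), "TIFF")
})

test_that("downscale follows the 50% pipeline geometry and area averaging", {
  ## the pipeline constant: 50% downscale halves each axis
  s <- sectionImage(randomRaster(1024, 1024, seed = 2), mpp = 0.5)
  d <- downscaleSection(s, 0.5)
  expect_equal(dim(sectionPixels(d))[1:2], c(512L, 512L))
  expect_equal(micronsPerPixel(d), 1.0)  # mpp divided by the factor

  ## factor 1 is the identity on pixels
  expect_identical(sectionPixels(downscaleSection(s, 1)), sectionPixels(s))

  ## area averaging preserves constant rasters exactly
  const <- sectionImage(array(100, c(10, 10, 3)))
  dc <- downscaleSection(const, 0.5)
  expect_equal(dim(sectionPixels(dc))[1:2], c(5L, 5L))
  expect_true(all(sectionPixels(dc) == 100))

  ## a 2x2 box mean is reproduced exactly at factor 0.5
  m <- matrix(c(10, 20, 30, 40), 2, 2)
  s2 <- sectionImage(array(rep(m, 3), c(2, 2, 3)))
  expect_equal(c(sectionPixels(downscaleSection(s2, 0.5))[1, 1, ]),
               rep(mean(m), 3))

  expect_error(downscaleSection(s, 0), "factor")
  expect_error(downscaleSection(s, 1.5), "factor")
})

test_that("tissue mask separates stained tissue from background glass", {
  white <- sectionImage(array(255, c(20, 20, 3)))
  expect_equal(sum(tissueMask(white)@mask), 0)

  red <- sectionImage(array(rep(c(200, 30, 30), each = 400), c(20, 20, 3)))
  expect_true(all(tissueMask(red)@mask))

  ## half white / half dark pink: tissue fraction 0.5, verified by a
  ## brute-force per-pixel scan with the same rule
  px <- array(255, c(20, 20, 3))
  px[11:20, , 1] <- 180; px[11:20, , 2] <- 100; px[11:20, , 3] <- 140
  s <- sectionImage(px)
  mask <- tissueMask(s)@mask
  manual <- 0L
  for (y in 1:20) for (x in 1:20) {
    lum <- sum(c(0.299, 0.587, 0.114) * px[y, x, ]) / 255
    mx <- max(px[y, x, ]); mn <- min(px[y, x, ])
    sat <- if (mx == 0) 0 else (mx - mn) / mx
    if (lum < 0.92 || sat > 0.08) manual <- manual + 1L
  }
  expect_equal(sum(mask), manual)
  expect_equal(mean(mask), 0.5)

  ## deterministic and idempotent in its parameters
  expect_identical(tissueMask(s)@mask, mask)
})

test_that("tiling lays out the 512-tile grid with padded edge tiles", {
  dark <- function(h, w) sectionImage(array(rep(c(150, 60, 100),
                                                each = h * w), c(h, w, 3)))
  ## 1024x1024 -> 2x2 full tiles at the documented origins
  g <- tileSection(dark(1024, 1024), tileSize = 512)
  m <- tileManifest(g)
  expect_equal(nrow(m), 4L)
  expect_equal(m[, c("y0", "x0")],
               data.frame(y0 = c(0L, 0L, 512L, 512L),
                          x0 = c(0L, 512L, 0L, 512L)),
               ignore_attr = TRUE)
  expect_true(all(m$valid_fraction == 1))

  ## exactly one tile for a tile-sized section
  g1 <- tileSection(dark(512, 512), tileSize = 512)
  expect_equal(nrow(tileManifest(g1)), 1L)
  expect_equal(tileManifest(g1)$valid_fraction, 1)

  ## 700x600: corner tile footprint is 188x88, padding is white
  g2 <- tileSection(dark(700, 600), tileSize = 512)
  m2 <- tileManifest(g2)
  corner <- which(m2$row == 1 & m2$col == 1)
  expect_equal(m2$valid_fraction[corner], (188 * 88) / 512^2)
  tile <- tilePixels(g2, corner)
  expect_true(all(tile[189:512, , ] == 255))
  expect_true(all(tile[, 89:512, ] == 255))

  expect_error(tileSection(dark(64, 64), tileSize = 0), "tileSize")
})

test_that("tiling partitions the raster and round-trips bit-exactly", {
  for (seed in 1:3) {
    h <- sample(200:400, 1); w <- sample(200:400, 1)
    s <- sectionImage(randomRaster(h, w, seed = seed))
    g <- tileSection(s, tileSize = 96)
    m <- tileManifest(g)
    ## partition: valid pixel counts sum to the raster area
    validPixels <- sum(m$valid_fraction * 96^2)
    expect_equal(validPixels, h * w)
    ## round trip
    expect_identical(sectionPixels(reassembleSection(g)), sectionPixels(s))
  }
})

test_that("low-tissue tiles are excluded from scoring but kept in the grid", {
  ## left half tissue-coloured, right half white glass
  px <- array(255, c(64, 128, 3))
  px[, 1:64, 1] <- 150; px[, 1:64, 2] <- 60; px[, 1:64, 3] <- 100
  g <- tileSection(sectionImage(px), tileSize = 64)
  m <- tileManifest(g)
  expect_equal(nrow(m), 2L)
  expect_equal(m$excluded, c(FALSE, TRUE))
  expect_equal(m$tissue_fraction, c(1, 0))
})

test_that("tile manifest TSV has the documented columns", {
  s <- sectionImage(randomRaster(100, 100, seed = 9), ident = "sec1")
  g <- tileSection(s, tileSize = 64)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTileManifest(g, path)
  tab <- read.delim(path)
  expect_named(tab, c("ident", "row", "col", "y0", "x0", "tile_size",
                      "valid_fraction", "tissue_fraction", "excluded"))
  expect_true(all(tab$excluded %in% 0:1))
})
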