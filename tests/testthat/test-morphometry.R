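test_that("positive area fractions match brute-force pixel counts", {
  prof <- stainProfile("synthetic")
  collagen <- textureParams()@palette["collagen", ]
  tissue <- textureParams()@palette["tissue", ]

  ## fully positive tissue: 100%
  allPos <- sectionImage(array(rep(collagen, each = 400), c(20, 20, 3)))
  expect_equal(areaPercent(positiveAreaFraction(allPos, prof)), 100)

  ## no positive pixels: 0%
  noPos <- sectionImage(array(rep(tissue, each = 400), c(20, 20, 3)))
  expect_equal(areaPercent(positiveAreaFraction(noPos, prof)), 0)

  ## constructed half/half mosaic: exactly 50%
  px <- array(0, c(20, 20, 3))
  for (ch in 1:3) {
    px[1:10, , ch] <- collagen[ch]
    px[11:20, , ch] <- tissue[ch]
  }
  half <- sectionImage(px)
  af <- positiveAreaFraction(half, prof)
  expect_equal(areaPercent(af), 50)
  expect_equal(af@nPositive, 200)
  expect_equal(af@nTissue, 400)

  ## all-background section: undefined fraction
  white <- sectionImage(array(255, c(8, 8, 3)))
  expect_error(positiveAreaFraction(white, prof), "undefined")
  ## but the full-raster denominator is always defined
  expect_equal(areaPercent(positiveAreaFraction(white, prof,
                                                denominator = "raster")), 0)
})

test_that("area fractions are additive over a disjoint tissue partition", {
  prof <- stainProfile("synthetic")
  set.seed(3)
  pal <- textureParams()@palette
  px <- array(0, c(30, 40, 3))
  which <- matrix(sample(2:3, 30 * 40, replace = TRUE), 30, 40)
  for (ch in 1:3) px[, , ch] <- pal[cbind(c(which), ch)]
  s <- sectionImage(px)
  whole <- positiveAreaFraction(s, prof)
  left <- positiveAreaFraction(sectionImage(px[, 1:20, , drop = FALSE]), prof)
  right <- positiveAreaFraction(sectionImage(px[, 21:40, , drop = FALSE]),
                                prof)
  pooled <- 100 * (left@nPositive + right@nPositive) /
    (left@nTissue + right@nTissue)
  expect_equal(areaPercent(whole), pooled, tolerance = 1e-12)
})

test_that("hue-window stain rules detect their colours", {
  psr <- stainProfile("PSR")
  red <- sectionImage(array(rep(c(200, 40, 60), each = 100), c(10, 10, 3)))
  expect_equal(areaPercent(positiveAreaFraction(red, psr)), 100)
  blue <- sectionImage(array(rep(c(60, 80, 175), each = 100), c(10, 10, 3)))
  expect_equal(areaPercent(positiveAreaFraction(blue, psr)), 0)
})

test_that("Archimedes lobule volume is mass over density", {
  expect_equal(volumeMl(lobuleVolumeFromDisplacement(0.25)), 0.25)
  expect_equal(volumeMl(lobuleVolumeFromDisplacement(0.25, 1.05)),
               0.25 / 1.05)
  v <- lobuleVolumeFromDisplacement(0.25)
  expect_equal(volumeMm3(v), 250)
  expect_equal(volumeUm3(v), 0.25e12)
  expect_error(lobuleVolumeFromDisplacement(0), "massG")
  expect_error(lobuleVolumeFromDisplacement(1, 0), "density")
})

test_that("whole-lobule marker volume is mean %-area times volume", {
  v25 <- lobuleVolumeFromDisplacement(0.25)
  expect_equal(volumeMl(wholeLobuleMarkerVolume(10, v25)), 0.025)
  expect_equal(volumeMl(wholeLobuleMarkerVolume(c(0, 0), v25)), 0)
  v1 <- lobuleVolumeFromDisplacement(1)
  mk <- wholeLobuleMarkerVolume(c(10, 20, 30), v1)
  expect_equal(volumeMl(mk), 0.2)
  expect_equal(mk@singleSectionMl, 0.1)
  ## linear in both mean %-area and lobule volume
  expect_equal(volumeMl(wholeLobuleMarkerVolume(c(20, 40, 60), v1)), 0.4)
  v2 <- lobuleVolumeFromDisplacement(2)
  expect_equal(volumeMl(wholeLobuleMarkerVolume(c(10, 20, 30), v2)), 0.4)
  expect_error(wholeLobuleMarkerVolume(numeric(0), v1), "fraction")
})

test_that("serial-section summaries report spread and representativeness", {
  eq <- serialSectionSummary(rep(12, 6))
  expect_equal(eq$cv, 0)
  expect_true(all(eq$perSection$deviation == 0))

  two <- serialSectionSummary(c(8, 12))
  expect_equal(two$mean, 10)
  expect_equal(two$perSection$relativeDeviation, c(-0.2, 0.2))
  expect_equal(two$spacingUm, 300)

  expect_error(serialSectionSummary(5), "sections")

  ## mean agrees with a brute-force mean on random inputs
  set.seed(9)
  for (i in 1:100) {
    f <- runif(sample(2:8, 1), 0, 40)
    expect_equal(serialSectionSummary(f)$mean, sum(f) / length(f),
                 tolerance = 1e-12)
  }
})

test_that("AreaFraction objects feed stereology directly", {
  prof <- stainProfile("synthetic")
  collagen <- textureParams()@palette["collagen", ]
  tissue <- textureParams()@palette["tissue", ]
  mk <- function(fracPos) {
    px <- array(0, c(10, 10, 3))
    n <- round(100 * fracPos)
    for (ch in 1:3) {
      px[, , ch] <- tissue[ch]
      if (n > 0) px[, , ch][seq_len(n)] <- collagen[ch]
    }
    positiveAreaFraction(sectionImage(px), prof)
  }
  fr <- list(mk(0.1), mk(0.2), mk(0.3))
  v <- lobuleVolumeFromDisplacement(1)
  expect_equal(volumeMl(wholeLobuleMarkerVolume(fr, v)), 0.2)
  expect_equal(serialSectionSummary(fr)$mean, 20)
})
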