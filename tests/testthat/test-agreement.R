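test_that("confusion matrices tally reference x predicted counts", {
  cm <- confusionMatrix(c(0, 0, 8, 8), c(0, 0, 8, 8), classes = c("0", "8"))
  expect_equal(unname(cm), rbind(c(2L, 0L), c(0L, 2L)))
  expect_equal(sum(cm), 4)
  anti <- confusionMatrix(c(0, 8), c(8, 0), classes = c("0", "8"))
  expect_equal(unname(anti), rbind(c(0L, 1L), c(1L, 0L)))
  expect_error(confusionMatrix(c(0, 1), c(0), classes = c("0", "1")),
               "length")
  expect_error(confusionMatrix("0", "9"), "class order")
  ## marginals match per-class reference counts on random labelings
  set.seed(7)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    ref <- sample(as.character(0:8), n, replace = TRUE)
    prd <- sample(as.character(0:8), n, replace = TRUE)
    cm <- confusionMatrix(ref, prd)
    expect_equal(rowSums(cm), table(factor(ref, levels = as.character(0:8))),
                 ignore_attr = TRUE)
    expect_equal(colSums(cm), table(factor(prd, levels = as.character(0:8))),
                 ignore_attr = TRUE)
  }
})

test_that("Cohen's kappa matches its closed-form cases", {
  ## perfect diagonal agreement
  expect_equal(kappaValue(cohenKappa(diag(c(5, 5)))), 1)
  ## chance-level: balanced truth, single predicted column
  k0 <- cohenKappa(rbind(c(5, 0), c(5, 0)))
  expect_equal(kappaValue(k0), 0)
  expect_equal(k0@pO, 0.5)
  expect_equal(k0@pE, 0.5)
  ## hand-evaluated mixed case: pO = 0.7, pE = 0.5, kappa = 0.4
  k <- cohenKappa(rbind(c(20, 5), c(10, 15)))
  expect_equal(k@pO, 0.7)
  expect_equal(k@pE, 0.5)
  expect_equal(kappaValue(k), 0.4)
  expect_error(cohenKappa(matrix(0, 2, 2)), "empty")
})

test_that("kappa is bounded, permutation-invariant and degenerate-safe", {
  set.seed(11)
  for (i in 1:60) {
    K <- sample(2:9, 1)
    cm <- matrix(rpois(K * K, 3), K, K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    k <- kappaValue(cohenKappa(cm))
    expect_gte(k, -1); expect_lte(k, 1)
    ## simultaneous row/column permutation leaves unweighted kappa alone
    p <- sample(K)
    expect_equal(kappaValue(cohenKappa(cm[p, p])), k, tolerance = 1e-12)
    ## on 2 classes, linear weights degenerate to the unweighted statistic
    cm2 <- matrix(rpois(4, 5), 2, 2); cm2[1, 1] <- cm2[1, 1] + 1
    expect_equal(kappaValue(cohenKappa(cm2, "linear")),
                 kappaValue(cohenKappa(cm2, "none")), tolerance = 1e-12)
  }
  ## diagonal with >= 2 classes is exactly 1
  expect_equal(kappaValue(cohenKappa(diag(c(3, 1, 7)))), 1)
  ## degenerate pE = 1: all mass in one cell
  kd <- cohenKappa(matrix(c(9, 0, 0, 0), 2, 2))
  expect_true(kd@degenerate)
  expect_equal(kappaValue(kd), 1)
})

test_that("weighted kappa penalises ordinal distance progressively", {
  ## constant +1-grade shift on a 0..8 scale
  ref <- rep(as.character(0:7), each = 5)
  prd <- as.character(as.integer(ref) + 1)
  cm <- confusionMatrix(ref, prd)
  kn <- kappaValue(cohenKappa(cm, "none"))
  kl <- kappaValue(cohenKappa(cm, "linear"))
  kq <- kappaValue(cohenKappa(cm, "quadratic"))
  expect_lt(kn, kl)
  expect_lt(kl, kq)  # near misses hurt quadratic least
  expect_lt(kn, 1)
})

test_that("agreement reports join tables, drop mismatches and report both levels", {
  scores <- data.frame(ident = paste0("s", 1:6),
                       score = c(0.2, 1.6, 3.4, 4.5, 6.1, 7.8))
  rep1 <- agreementReport(scores, scores, level = "section")
  expect_equal(kappaValue(rep1$kappa$none), 1)
  expect_equal(rep1$concordance, 1)
  ## constant +1 shift: imperfect kappa, sub-unity concordance
  shifted <- transform(scores, score = pmin(score + 1, 8))
  rep2 <- agreementReport(scores, shifted, level = "section")
  expect_lt(kappaValue(rep2$kappa$none), 1)
  expect_lt(rep2$concordance, 1)
  ## unmatched idents are dropped with a warning and counted
  extra <- rbind(scores, data.frame(ident = "s99", score = 2))
  expect_warning(rep3 <- agreementReport(extra, scores, level = "section"),
                 "unmatched")
  expect_equal(rep3$nDropped, 1L)
  expect_error(agreementReport(scores,
                               data.frame(ident = "zz", score = 1),
                               level = "section"), "matched")

  ## tile level: exact agreement on a small annotation table
  tiles <- data.frame(ident = "s1", row = rep(0:1, each = 2),
                      col = rep(0:1, 2), label = c("0", "3", "5", "8"))
  rt <- agreementReport(tiles, tiles, level = "tile")
  expect_equal(kappaValue(rt$kappa$none), 1)
  expect_equal(rt$n, 4L)
})

test_that("Lin's concordance follows its closed form", {
  x <- c(1, 2, 3, 4)
  expect_equal(linConcordance(x, x), 1)
  y <- x + 2
  ## location shift: 2*sxy / (sx2 + sy2 + 4)
  sxy <- mean((x - mean(x))^2)
  expect_equal(linConcordance(x, y), 2 * sxy / (2 * sxy + 4))
  expect_error(linConcordance(1, 2:3), "paired")
})
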