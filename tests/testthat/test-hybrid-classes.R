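test_that("hybrid index and heterozygosity follow the allele counts", {
  # loci as rows, individuals as columns
  g <- cbind(allHet = rep(1L, 6), pureEast = rep(2L, 6), pureWest = rep(0L, 6))
  pts <- ancestryPoints(g)
  expect_equal(pts$hybridIndex, c(0.5, 1, 0))
  expect_equal(pts$heterozygosity, c(1, 0, 0))
  # hand count over 4 diagnostic loci
  one <- matrix(c(2L, 1L, 0L, 1L), 4, 1, dimnames = list(NULL, "t"))
  p1 <- ancestryPoints(one)
  expect_equal(p1$hybridIndex, 0.5)
  expect_equal(p1$heterozygosity, 0.5)
})

test_that("ancestry is invariant to locus order and individual missingness", {
  set.seed(51)
  g <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 50, 4)
  colnames(g) <- paste0("i", 1:4)
  a <- ancestryPoints(g)
  b <- ancestryPoints(g[sample(50), , drop = FALSE])
  expect_equal(a[, -1], b[, -1])
  # dropping loci that are missing anyway changes nothing
  miss <- is.na(g[, 1])
  expect_equal(ancestryPoints(g[!miss, 1, drop = FALSE])$hybridIndex,
               a$hybridIndex[1])
  allNA <- matrix(NA_integer_, 5, 1, dimnames = list(NULL, "ghost"))
  expect_error(ancestryPoints(allNA), "ghost")
})

test_that("the triangle bound H <= 2 min(HI, 1-HI) is combinatorial", {
  set.seed(53)
  g <- matrix(sample(c(0:2, NA), 3000, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 100, 30)
  pts <- ancestryPoints(g)
  expect_true(all(pts$heterozygosity <=
                    2 * pmin(pts$hybridIndex, 1 - pts$hybridIndex) + 1e-12))
})

test_that("crossing pools fixed for alternate alleles forces heterozygosity", {
  p <- diagnosticPools(nLoci = 20L, nPer = 10L)
  off <- simulateCross(p$west, p$east, nOffspring = 50L, seed = 2L)
  expect_true(all(off == 1L))
  expect_identical(off, simulateCross(p$west, p$east, 50L, seed = 2L))
  expect_equal(eval(formals(simulateCross)$nOffspring), 500L)
  expect_error(simulateCross(p$west[, 0], p$east, 10L), "empty")
})

test_that("offspring allele frequencies obey Mendelian sampling", {
  p <- semiDiagnosticPools(nLoci = 20L, nPer = 60L, pw = 0.2, pe = 0.8)
  off <- simulateCross(p$west, p$east, nOffspring = 5000L, seed = 7L)
  expected <- (rowMeans(p$west) / 2 + rowMeans(p$east) / 2) / 2
  for (l in 1:20) {
    obs <- mean(off[l, ]) / 2
    se <- sqrt(expected[l] * (1 - expected[l]) / (2 * 5000))
    expect_lt(abs(obs - expected[l]), 3 * se)
  }
  # missing parental calls propagate to offspring
  pm <- p
  pm$west[1, ] <- NA
  offm <- simulateCross(pm$west, pm$east, 100L, seed = 8L)
  expect_true(all(is.na(offm[1, ])))
  expect_true(all(!is.na(offm[-1, ])))
})

test_that("diagnostic pools give the textbook class means", {
  p <- diagnosticPools(nLoci = 101L, nPer = 50L)
  clouds <- buildClassClouds(p$west, p$east, nPerClass = 500L, seed = 5L)
  expect_named(clouds, c("pure_west", "pure_east", "F1", "F2",
                         "BC_west", "BC_east"))
  expect_equal(nrow(clouds$F1@points), 500L)
  # F1 collapses to the apex of the triangle
  expect_true(all(clouds$F1@points[, "hybridIndex"] == 0.5))
  expect_true(all(clouds$F1@points[, "heterozygosity"] == 1))
  # Mendelian expectations, 3 SE at n = 500 x 101 loci
  seHI <- 3 * sqrt(0.5 * 0.5 / (2 * 101)) / sqrt(500)
  expect_equal(unname(clouds$F2@center["hybridIndex"]), 0.5,
               tolerance = 5 * seHI)
  expect_equal(unname(clouds$F2@center["heterozygosity"]), 0.5,
               tolerance = 0.01)
  expect_equal(unname(clouds$BC_east@center["hybridIndex"]), 0.75,
               tolerance = 0.01)
  expect_equal(unname(clouds$BC_east@center["heterozygosity"]), 0.5,
               tolerance = 0.01)
  expect_equal(unname(clouds$BC_west@center["hybridIndex"]), 0.25,
               tolerance = 0.01)
})

test_that("semi-diagnostic loci dilute F1 heterozygosity as expected", {
  pw <- 0.1; pe <- 0.9
  p <- semiDiagnosticPools(nLoci = 101L, nPer = 80L, pw = pw, pe = pe)
  clouds <- buildClassClouds(p$west, p$east, nPerClass = 500L, seed = 6L)
  hF1 <- clouds$F1@center["heterozygosity"]
  expect_lt(hF1, 1)
  # analytic expectation: P(het) = pw (1 - pe) + pe (1 - pw) per locus with
  # gametes drawn from the realized pool frequencies
  fw <- mean(rowMeans(p$west) / 2)
  fe <- mean(rowMeans(p$east) / 2)
  expected <- fw * (1 - fe) + fe * (1 - fw)
  expect_equal(unname(hF1), expected, tolerance = 0.03)
})

test_that("classification gates points by Mahalanobis distance", {
  p <- semiDiagnosticPools(nLoci = 101L, nPer = 80L)
  clouds <- buildClassClouds(p$west, p$east, nPerClass = 500L, seed = 9L)
  atMean <- data.frame(hybridIndex = clouds$F1@center[1],
                       heterozygosity = clouds$F1@center[2])
  expect_equal(classifyHybrids(atMean, clouds)$class, "F1")
  # the lower center of the triangle is far from every early-generation cloud
  far <- data.frame(hybridIndex = 0.5, heterozygosity = 0)
  expect_equal(classifyHybrids(far, buildClassClouds(
    diagnosticPools(101L, 50L)$west, diagnosticPools(101L, 50L)$east,
    500L, seed = 1L))$class, "advanced/unassigned")
  expect_error(classifyHybrids(atMean, list()), "no clouds")
})

test_that("an advanced backcross swarm contains no F1-like individuals", {
  p <- semiDiagnosticPools(nLoci = 101L, nPer = 80L)
  clouds <- buildClassClouds(p$west, p$east, nPerClass = 500L, seed = 11L)
  # third-generation backcrosses toward the east
  f1 <- simulateCross(p$west, p$east, 300L, seed = 12L)
  bc1 <- simulateCross(f1, p$east, 300L, seed = 13L)
  bc2 <- simulateCross(bc1, p$east, 300L, seed = 14L)
  bc3 <- simulateCross(bc2, p$east, 300L, seed = 15L)
  cls <- classifyHybrids(ancestryPoints(bc3), clouds)
  expect_equal(sum(cls$class == "F1"), 0L)
  expect_gt(mean(cls$class %in% c("BC_east", "pure_east",
                                  "advanced/unassigned")), 0.5)
})
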