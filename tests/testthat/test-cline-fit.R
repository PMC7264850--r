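test_that("fitting is deterministic given table and configuration", {
  m <- clineModel("I", center = 0, width = 2000, pmin = 0.1, pmax = 0.9)
  tab <- generateBinTable(m, seq(-4500, 4500, length.out = 19), 40, seed = 2L)
  f1 <- fitCline(tab, "I", quickFitConfig(5L))
  f2 <- fitCline(tab, "I", quickFitConfig(5L))
  expect_identical(f1@samples, f2@samples)
  expect_identical(bestModel(f1)@center, bestModel(f2)@center)
  expect_identical(supportIntervals(f1), supportIntervals(f2))
})

test_that("the MCMC maximum dominates the generating parameters", {
  set.seed(31)
  for (rep in 1:3) {
    m <- clineModel("I", center = runif(1, -500, 500),
                    width = runif(1, 800, 3000),
                    pmin = runif(1, 0, 0.2), pmax = runif(1, 0.8, 1))
    tab <- generateBinTable(m, seq(-5000, 5000, length.out = 19), 60,
                            seed = 100 + rep)
    f <- fitCline(tab, "I", quickFitConfig(rep))
    expect_gte(f@logLik, clineLogLikFreq(m, tab) - 1e-6)
  }
})

test_that("support intervals contain the estimate and nest by cutoff", {
  m <- clineModel("I", center = 0, width = 2000, pmin = 0.1, pmax = 0.9)
  tab <- generateBinTable(m, seq(-4500, 4500, length.out = 19), 40, seed = 4L)
  f <- fitCline(tab, "I", quickFitConfig(6L))
  iv <- supportIntervals(f)
  expect_true(all(iv[, "low"] <= iv[, "high"]))
  est <- c(center = bestModel(f)@center, width = bestModel(f)@width,
           pmin = bestModel(f)@pmin, pmax = bestModel(f)@pmax)
  for (p in rownames(iv)) {
    expect_gte(est[p], iv[p, "low"])
    expect_lte(est[p], iv[p, "high"])
  }
  i1 <- twoLLInterval(f@samples, f@samples$lnL, "center", cutoff = 1)
  i2 <- twoLLInterval(f@samples, f@samples$lnL, "center", cutoff = 2)
  i3 <- twoLLInterval(f@samples, f@samples$lnL, "center", cutoff = 3)
  expect_true(i2[1] <= i1[1] && i1[2] <= i2[2])
  expect_true(i3[1] <= i2[1] && i2[2] <= i3[2])
})

test_that("a point-mass sample gives a point interval", {
  s <- data.frame(center = rep(42, 150))
  expect_equal(twoLLInterval(s, rep(-1, 150), "center"), c(42, 42))
  expect_error(twoLLInterval(s[1:10, , drop = FALSE], rep(-1, 10), "center"),
               "100")
})

test_that("the 2-unit interval of a Gaussian log-likelihood is about 2 sigma", {
  # quadratic log-likelihood in one parameter: lnL = -(x - 3)^2 / (2 s^2)
  s <- 0.7
  x <- seq(3 - 5 * s, 3 + 5 * s, length.out = 5000)
  lnl <- -(x - 3)^2 / (2 * s^2)
  iv <- twoLLInterval(data.frame(center = x), lnl, "center")
  expect_equal(iv[2] - iv[1], 2 * 2 * s, tolerance = 0.1)
})

test_that("a single bin leaves the width unidentifiable", {
  tab <- frequencyBinTable(distance = 0, n = 50, count = 25)
  f <- fitCline(tab, "I", quickFitConfig(8L))
  iv <- supportIntervals(f)["width", ]
  bounds <- zoneclines:::.defaultBounds(c(0, 0))
  # the interval spans essentially the whole permitted width range
  expect_lt(iv["low"], 2)
  expect_gt(iv["high"], 0.5 * bounds["width", "high"])
})

test_that("flat data select the null model; AIC respects nesting", {
  flat <- clineModel("I", center = 0, width = 1000, pmin = 0.4, pmax = 0.4)
  tab <- generateBinTable(flat, seq(-4000, 4000, length.out = 15), 60,
                          seed = 12L)
  sel <- selectClineModel(tab, quickFitConfig(3L))
  expect_true(isNullCline(sel))
  expect_equal(sel@modelType, "null")
  aic <- aicTable(sel)
  expect_named(aic, c("null", "I", "II", "III"))
  # nested models cannot lose likelihood beyond MCMC noise
  m <- clineModel("I", center = 0, width = 2000, pmin = 0.1, pmax = 0.9)
  tab2 <- generateBinTable(m, seq(-4500, 4500, length.out = 19), 40,
                           seed = 14L)
  fI <- fitCline(tab2, "I", quickFitConfig(2L))
  fII <- fitCline(tab2, "II", quickFitConfig(2L))
  fIII <- fitCline(tab2, "III", quickFitConfig(2L))
  expect_gte(fII@logLik, fI@logLik - 0.5)
  expect_gte(fIII@logLik, fII@logLik - 0.5)
})

test_that("trait characters without a distance trend are gated to null", {
  set.seed(41)
  tab <- traitBinTable(distance = seq(-4000, 4000, length.out = 15),
                       n = rep(10, 15), mean = rnorm(15, 0.5, 0.02),
                       variance = rep(0.04, 15))
  sel <- selectClineModel(tab, quickFitConfig(4L))
  expect_true(isNullCline(sel))
  expect_gte(sel@details$gate_p, 0.05)
  # a clear clinal trait passes the gate and gets a sigmoid fit
  m <- clineModel("I", center = 0, width = 2000, pmin = 0.1, pmax = 0.9)
  tab2 <- traitBinTable(distance = tab$distance, n = rep(12, 15),
                        mean = clineValue(m, tab$distance) +
                          rnorm(15, 0, 0.02),
                        variance = rep(0.02, 15))
  sel2 <- selectClineModel(tab2, quickFitConfig(4L))
  expect_false(isNullCline(sel2))
  expect_lt(sel2@details$gate_p, 0.05)
  expect_equal(bestModel(sel2)@center, 0, tolerance = 400)
})

test_that("fixing parameters removes them from sampling and from k", {
  m <- clineModel("I", center = 0, width = 2000, pmin = 0, pmax = 1)
  tab <- generateBinTable(m, seq(-4500, 4500, length.out = 19), 60, seed = 6L)
  f <- fitCline(tab, "I", quickFitConfig(9L), fixed = c(pmin = 0, pmax = 1))
  expect_equal(f@k, 2L)
  expect_equal(bestModel(f)@pmin, 0)
  expect_equal(bestModel(f)@pmax, 1)
  expect_setequal(rownames(supportIntervals(f)), c("center", "width"))
})

test_that("center recovery holds across seeds (reduced replicate check)", {
  m <- clineModel("I", center = 0, width = 2000, pmin = 0.1, pmax = 0.9)
  hits <- 0
  errs <- numeric(20)
  for (i in 1:20) {
    tab <- generateBinTable(m, seq(-4500, 4500, length.out = 19), 40,
                            seed = 500 + i)
    f <- fitCline(tab, "I", quickFitConfig(i))
    iv <- supportIntervals(f)["center", ]
    hits <- hits + (iv["low"] <= 0 && 0 <= iv["high"])
    errs[i] <- abs(bestModel(f)@center)
  }
  expect_gte(hits, 17)
  expect_lt(median(errs), 200)
})
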