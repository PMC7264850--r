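test_that("sigmoid cline evaluates to its closed form", {
  m <- clineModel("I", center = 0, width = 2000, pmin = 0, pmax = 1)
  expect_equal(clineValue(m, 0), 0.5)
  expect_equal(clineValue(m, 1000), 1 / (1 + exp(-2)), tolerance = 1e-12)
  # midpoint is (pmin+pmax)/2 for any endpoints
  m2 <- clineModel("I", center = 500, width = 800, pmin = 0.2, pmax = 0.8)
  expect_equal(clineValue(m2, 500), 0.5)
  expect_error(clineValue(m, NaN), "finite")
})

test_that("null model is the straight line through the span endpoints", {
  m <- clineModel("null", pmin = 0.3, pmax = 0.7, span = c(-1000, 1000))
  expect_equal(clineValue(m, -1000), 0.3)
  expect_equal(clineValue(m, 1000), 0.7)
  expect_equal(clineValue(m, 0), 0.5)
  # clamped beyond the span
  expect_equal(clineValue(m, -5000), 0.3)
})

test_that("far-attached tails reduce model II to model I", {
  w <- 2000
  mI <- clineModel("I", center = 0, width = w, pmin = 0, pmax = 1)
  mII <- clineModel("II", center = 0, width = w, pmin = 0, pmax = 1,
                    deltaL = 10 * w, tauL = 0.3)
  d <- seq(-5 * w, 5 * w, length.out = 400)
  expect_lt(max(abs(clineValue(mII, d) - clineValue(mI, d))), 1e-6)
})

test_that("tails join the sigmoid continuously, C1 when tau = 1", {
  for (tau in c(0.1, 0.5, 1)) for (delta in c(200, 1500)) {
    m <- clineModel("III", center = 100, width = 1800, pmin = 0.05,
                    pmax = 0.95, deltaL = delta, tauL = tau,
                    deltaR = delta / 2, tauR = tau)
    for (a in c(100 - delta, 100 + delta / 2)) {
      expect_lt(abs(clineValue(m, a - 1e-9) - clineValue(m, a)), 1e-6)
      expect_lt(abs(clineValue(m, a + 1e-9) - clineValue(m, a)), 1e-6)
      if (tau == 1) {
        h <- 1e-4
        dl <- (clineValue(m, a) - clineValue(m, a - h)) / h
        dr <- (clineValue(m, a + h) - clineValue(m, a)) / h
        expect_lt(abs(dl - dr), 1e-6)
      }
    }
  }
})

test_that("clines are monotone and bounded for all model types", {
  set.seed(11)
  d <- seq(-20000, 20000, length.out = 801)
  for (rep in 1:20) {
    ty <- sample(c("I", "II", "III"), 1)
    p <- sort(runif(2))
    m <- clineModel(ty, center = runif(1, -2000, 2000),
                    width = runif(1, 200, 5000),
                    pmin = p[1], pmax = p[2],
                    deltaL = if (ty != "I") runif(1, 0, 3000) else NA,
                    tauL = if (ty != "I") runif(1, 0.05, 1) else NA,
                    deltaR = if (ty == "III") runif(1, 0, 3000) else NA,
                    tauR = if (ty == "III") runif(1, 0.05, 1) else NA)
    v <- clineValue(m, d)
    expect_true(all(diff(v) >= -1e-12))
    expect_true(all(v >= p[1] - 1e-12 & v <= p[2] + 1e-12))
    # decreasing cline mirrors the increasing one
    mdec <- clineModel("I", center = 0, width = 1000, pmin = p[2], pmax = p[1])
    expect_true(all(diff(clineValue(mdec, d)) <= 1e-12))
  }
})

test_that("smaller tau means longer tails (slower decay)", {
  base <- clineValue(clineModel("I", center = 0, width = 2000), -8000)
  dev <- vapply(c(0.9, 0.5, 0.1), function(tau) {
    m <- clineModel("II", center = 0, width = 2000, deltaL = 500, tauL = tau)
    abs(clineValue(m, -8000) - base)
  }, 0)
  expect_true(all(diff(dev) > 0))
})

test_that("binomial log-likelihood matches hand computation and is additive", {
  m <- clineModel("I", center = 0, width = 1000, pmin = 0.5, pmax = 0.5)
  one <- frequencyBinTable(distance = 0, n = 10, count = 5)
  expect_equal(clineLogLikFreq(m, one), 10 * log(0.5), tolerance = 1e-12)
  two <- frequencyBinTable(distance = c(-500, 500), n = c(10, 20),
                           count = c(5, 12))
  a <- frequencyBinTable(distance = -500, n = 10, count = 5)
  b <- frequencyBinTable(distance = 500, n = 20, count = 12)
  expect_equal(clineLogLikFreq(m, two),
               clineLogLikFreq(m, a) + clineLogLikFreq(m, b))
  expect_error(clineLogLikFreq(m, two[0, ]), "empty")
})

test_that("the saturated prediction maximizes the binomial likelihood", {
  # the null model's straight line passes exactly through two endpoint bins
  tab <- frequencyBinTable(distance = c(-2000, 2000), n = c(40, 40),
                           count = c(8, 32))
  exact <- clineModel("null", pmin = 0.2, pmax = 0.8, span = c(-2000, 2000))
  expect_equal(clineValue(exact, tab$distance), tab$count / tab$n,
               tolerance = 1e-12)
  llExact <- clineLogLikFreq(exact, tab)
  for (shift in c(-0.1, 0.05, 0.2))
    expect_lt(clineLogLikFreq(
      clineModel("null", pmin = 0.2 + shift, pmax = 0.8 - shift,
                 span = c(-2000, 2000)), tab), llExact)
})

test_that("trait log-likelihood matches a Gaussian density-product oracle", {
  m <- clineModel("I", center = 0, width = 1500, pmin = 0.1, pmax = 0.9)
  tab <- traitBinTable(distance = c(-1200, 0, 900), n = c(5, 8, 6),
                       mean = c(0.15, 0.52, 0.81),
                       variance = c(0.01, 0.02, 0.015))
  mu <- clineValue(m, tab$distance)
  oracle <- sum(dnorm(tab$mean, mu, sqrt(tab$variance / tab$n), log = TRUE))
  expect_equal(clineLogLikTrait(m, tab), oracle, tolerance = 1e-9)
  # residual-free fit has zero quadratic terms
  exact <- traitBinTable(distance = tab$distance, n = tab$n,
                         mean = mu, variance = tab$variance)
  expect_equal(clineLogLikTrait(m, exact),
               sum(-0.5 * log(2 * pi * tab$variance / tab$n)),
               tolerance = 1e-9)
  # doubling every n doubles the quadratic penalty
  tab2 <- traitBinTable(distance = tab$distance, n = 2 * tab$n,
                        mean = tab$mean, variance = tab$variance)
  quad1 <- clineLogLikTrait(m, tab) - sum(-0.5 * log(2 * pi * tab$variance / tab$n))
  quad2 <- clineLogLikTrait(m, tab2) -
    sum(-0.5 * log(2 * pi * tab$variance / (2 * tab$n)))
  expect_equal(quad2, 2 * quad1, tolerance = 1e-9)
})

test_that("trait standardization applies transforms then min-max scales", {
  expect_equal(standardizeTrait(c(1, 2, 3), "none")$values, c(0, 0.5, 1))
  s <- standardizeTrait(c(1, exp(1), exp(2)), "log")
  expect_equal(s$values, c(0, 0.5, 1), tolerance = 1e-12)
  expect_equal(s$invert(c(0, 0.5, 1)), c(1, exp(1), exp(2)),
               tolerance = 1e-12)
  s2 <- standardizeTrait(c(0, 1, 4), "sqrt")
  expect_equal(s2$values, c(0, 0.5, 1))
  expect_error(standardizeTrait(c(1, -2, 3), "log", ids = c("a", "b", "c")),
               "b")
  expect_warning(out <- standardizeTrait(c(2, 2, 2), "none"), "constant")
  expect_equal(out$values, c(0.5, 0.5, 0.5))
})

test_that("deltaP is the absolute frequency change across the zone", {
  expect_equal(deltaP(clineModel("I", 0, 1000, pmin = 0.02, pmax = 0.99)), 0.97)
  expect_equal(deltaP(clineModel("I", 0, 1000, pmin = 0.5, pmax = 0.5)), 0)
  # decreasing cline (western value higher), as for floral characters
  expect_equal(deltaP(clineModel("I", 0, 1000, pmin = 0.71, pmax = 0.41)), 0.30)
})

test_that("model construction enforces the per-type invariants", {
  expect_error(clineModel("I", center = 0, width = -5), "width")
  expect_error(clineModel("II", center = 0, width = 100, deltaL = 100,
                          tauL = 1.5), "tauL")
  expect_error(clineModel("I", center = 0, width = 100, deltaL = 5,
                          tauL = 0.5), "no tail")
  expect_silent(clineModel("III", center = 0, width = 100, deltaL = 0,
                           tauL = 1, deltaR = 10, tauR = 0.2))
})
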