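test_that("equirectangular projection has the closed-form arc lengths", {
  co <- data.frame(tree_id = c("a", "b", "c"),
                   lon = c(-115.5, -115.5, -115.49),
                   lat = c(37.46, 37.47, 37.46))
  pr <- projectCoordinates(co)
  # centroid maps to the origin
  expect_equal(mean(pr$x), 0, tolerance = 1e-9)
  expect_equal(mean(pr$y), 0, tolerance = 1e-9)
  # 0.01 degrees of latitude = R * 0.01 * pi/180 = 1111.95 m
  expect_equal(pr$y[2] - pr$y[1], 6371000 * 0.01 * pi / 180,
               tolerance = 1e-9)
  expect_equal(pr$y[2] - pr$y[1], 1112.0, tolerance = 1e-3)
  # longitude arc shortened by cos(latitude)
  expect_equal(pr$x[3] - pr$x[1],
               6371000 * 0.01 * pi / 180 * cos(mean(co$lat) * pi / 180),
               tolerance = 1e-9)
})

test_that("planar input passes through; mixed input is rejected", {
  pl <- data.frame(tree_id = "a", x = 10, y = 20)
  expect_identical(projectCoordinates(pl), pl)
  expect_error(projectCoordinates(data.frame(x = 1, y = 2, lon = 3, lat = 4)),
               "both")
  expect_error(projectCoordinates(data.frame(lon = 200, lat = 10)), "long")
})

test_that("signed distance is the perpendicular distance with a side sign", {
  vertical <- cbind(x = c(0, 0), y = c(-100, 100))
  expect_equal(signedDistance(3, 4, vertical, c(-10, 0)), 3)
  expect_equal(signedDistance(-3, 4, vertical, c(-10, 0)), -3)
  expect_equal(signedDistance(0, 50, vertical, c(-10, 0)), 0)
  expect_error(signedDistance(1, 1, cbind(c(5, 5), c(5, 5)), c(0, 0)),
               "degenerate")
})

test_that("polyline distance agrees with a brute-force oracle", {
  set.seed(7)
  t <- seq(0, 2 * pi, length.out = 40)
  verts <- cbind(x = 1000 * t, y = 800 * sin(t))
  px <- runif(100, -500, 7000)
  py <- runif(100, -2000, 2000)
  d <- abs(signedDistance(px, py, verts, c(-1e5, 0)))
  # independent oracle: 1-D minimization along every segment
  bruteForce <- function(x0, y0) {
    min(vapply(seq_len(nrow(verts) - 1), function(i) {
      f <- function(s) {
        sqrt((verts[i, 1] + s * (verts[i + 1, 1] - verts[i, 1]) - x0)^2 +
             (verts[i, 2] + s * (verts[i + 1, 2] - verts[i, 2]) - y0)^2)
      }
      min(optimize(f, c(0, 1), tol = 1e-12)$objective, f(0), f(1))
    }, 0))
  }
  for (k in seq_along(px))
    expect_lt(abs(d[k] - bruteForce(px[k], py[k])), 1e-6)
})

test_that("the 0.5 contour of a logistic surface sits at the midpoint", {
  set.seed(3)
  x <- runif(400, -4000, 4000)
  y <- runif(400, 0, 6000)
  q <- plogis(4 * (x - 500) / 1500)
  ctr <- estimateContour(x, y, q, gridResolution = 150)
  v <- contourVertices(ctr)
  expect_lt(max(abs(v[, 1] - 500)), 150)
  expect_error(estimateContour(x, y, q * 0.3, gridResolution = 150,
                               level = 0.5), "no contour")
})

test_that("a sinusoidal zone center is recovered within the grid scale", {
  cfg <- zoneConfig(nTrees = 700L, nSnps = 5L, contourShape = "sinusoid",
                    contourAmplitude = 800, contourPeriod = 5000, seed = 9L)
  zone <- generateZone(cfg)
  td <- treeData(zone)
  grid <- 200
  ctr <- estimateContour(td$x, td$y, td$qTrue, gridResolution = grid)
  est <- contourVertices(ctr)
  truth <- contourVertices(trueContour(cfg, 2000L))
  # one-sided Hausdorff distances via the package's own distance kernel
  dEst <- max(abs(signedDistance(est[, 1], est[, 2], truth, c(-1e6, 4000))))
  dTrue <- max(abs(signedDistance(truth[, 1], truth[, 2], est, c(-1e6, 4000))))
  expect_lt(max(dEst, dTrue), 2 * grid)
})

test_that("binning conserves trees, orders bins, and collapses small ones", {
  set.seed(21)
  d <- runif(200, -3000, 3000)
  b <- makeBins(d, binWidth = 250, minPerBin = 3)
  bins <- attr(b, "bins")
  expect_equal(sum(bins$nTrees), 200)
  expect_true(all(bins$nTrees >= 3))
  expect_true(all(diff(bins$meanDistance) > 0))
  expect_setequal(b$id, seq_along(d))
  # per-bin mean distance equals the mean over members
  for (i in bins$bin)
    expect_equal(bins$meanDistance[bins$bin == i],
                 mean(b$distance[b$bin == i]))
})

test_that("binning handles degenerate and sparse inputs", {
  one <- makeBins(rep(123.4, 7))
  expect_equal(nrow(attr(one, "bins")), 1L)
  expect_equal(attr(one, "bins")$nTrees, 7L)
  expect_error(makeBins(c(1, 2), minPerBin = 3), "fewer")
  # a far-flung singleton tree gets merged inward, ids conserved
  d <- c(rep(0, 5), rep(300, 4), 5000)
  b <- makeBins(d, binWidth = 250, minPerBin = 3)
  expect_equal(sort(unname(unlist(tapply(b$id, b$bin, identity)))), 1:10)
  expect_true(all(attr(b, "bins")$nTrees >= 3))
})

test_that("collapsing merges the under-filled bin toward the zone center", {
  # bins: [-1000] n=5, [0] n=2 (under), [250] n=5 -> the n=2 bin at the
  # center must merge with the neighbor whose center is nearer zero
  d <- c(rep(-1000, 5), rep(10, 2), rep(260, 5))
  b <- makeBins(d, binWidth = 250, minPerBin = 3)
  bins <- attr(b, "bins")
  expect_equal(nrow(bins), 2L)
  expect_equal(sort(bins$nTrees), c(5L, 7L))
  # the two trees at distance 10 ended up with the 260 m group
  expect_equal(unique(b$bin[b$distance > 0]), b$bin[b$distance == 260][1])
})
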