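test_that("radiusFromArea inverts the circle area", {
  expect_equal(radiusFromArea(pi), 1)
  expect_equal(radiusFromArea(4 * pi), 2)
  expect_error(radiusFromArea(0), class = "invalidInputError")
  expect_error(radiusFromArea(-1), class = "invalidInputError")
})

test_that("lensArea matches the closed form in all three branches", {
  expect_equal(lensArea(0, 1, 1), pi)
  expect_equal(lensArea(2, 1, 1), 0)
  expect_equal(lensArea(3, 1, 1), 0)
  expect_equal(lensArea(0.5, 1, 0.25), pi * 0.25^2)   # full inclusion
  expect_equal(lensArea(1, 1, 1), 2 * pi / 3 - sqrt(3) / 2, tolerance = 1e-12)
  # vectorized
  expect_equal(lensArea(c(0, 1, 2), 1, 1),
               c(pi, 2 * pi / 3 - sqrt(3) / 2, 0))
})

test_that("lensArea is strictly decreasing in the crossing regime", {
  set.seed(42)
  for (i in 1:25) {
    r1 <- runif(1, 0.2, 3)
    r2 <- runif(1, 0.2, 3)
    d <- seq(abs(r1 - r2) + 1e-6, r1 + r2 - 1e-6, length.out = 100)
    a <- lensArea(d, r1, r2)
    expect_true(all(diff(a) < 0))
  }
})

test_that("solveDistance round-trips the lens area within tolerance", {
  expect_equal(solveDistance(1, 1, pi), 0)
  expect_equal(solveDistance(1, 1, 0), 2)
  expect_equal(solveDistance(1, 1, 2 * pi / 3 - sqrt(3) / 2), 1,
               tolerance = 1e-6)
  expect_error(solveDistance(1, 0.5, 1.0), class = "infeasibleOverlapError")
  expect_error(solveDistance(-1, 1, 0.1), class = "invalidInputError")

  set.seed(7)
  for (i in 1:100) {
    r1 <- runif(1, 0.2, 4)
    r2 <- runif(1, 0.2, 4)
    target <- runif(1, 0, pi * min(r1, r2)^2)
    d <- solveDistance(r1, r2, target, tol = 1e-9)
    expect_lte(abs(lensArea(d, r1, r2) - target), 1e-9)
  }
})

test_that("placeThreeCircles builds the unique triangle of centers", {
  a <- lensArea(1.2, 1, 1)
  arr <- placeThreeCircles(1, 1, 1, a, a, a)
  expect_equal(arr@dAB, arr@dBC)
  expect_equal(arr@dAB, arr@dAC)
  expect_equal(arr@dAB, 1.2, tolerance = 1e-6)
  # canonical orientation: C above the AB axis
  expect_gt(arr@circles[[3]]@center[2], 0)

  disj <- placeThreeCircles(1, 0.8, 0.5, 0, 0, 0)
  cc <- lapply(disj@circles, function(s) s@center)
  rr <- vapply(disj@circles, function(s) s@radius, numeric(1))
  for (p in list(c(1, 2), c(2, 3), c(1, 3)))
    expect_gt(sqrt(sum((cc[[p[1]]] - cc[[p[2]]])^2)), rr[p[1]] + rr[p[2]])

  big <- lensArea(0.1, 1, 1)
  expect_error(placeThreeCircles(1, 1, 1, big, big, 0),
               class = "unrealizableArrangementError")
})

test_that("the sampling oracle agrees with closed forms", {
  o <- regionAreasAndCentroids(list(Circle(c(0.3, -0.2), 1)), 2e5, seed = 11)
  expect_lt(abs(o$areas[["1"]] - pi), 3 * mcAreaSE(o, "1"))
  expect_equal(o$centroids[["1"]], c(0.3, -0.2), tolerance = 0.02)

  disj <- list(Circle(c(0, 0), 1), Circle(c(3, 0), 1))
  expect_equal(regionAreasAndCentroids(disj, 1e5, 1)$areas[["12"]], 0)

  two <- list(Circle(c(0, 0), 1), Circle(c(1, 0), 1))
  o2 <- regionAreasAndCentroids(two, 5e5, seed = 3)
  expect_lt(abs(o2$areas[["12"]] - lensArea(1, 1, 1)), 3 * mcAreaSE(o2, "12"))

  # deterministic for a fixed seed, and leaves the caller's RNG alone
  set.seed(123); before <- runif(1)
  set.seed(123)
  a <- regionAreasAndCentroids(two, 1e4, seed = 5)$areas
  after <- runif(1)
  b <- regionAreasAndCentroids(two, 1e4, seed = 5)$areas
  expect_identical(a, b)
  expect_identical(before, after)
})

test_that("ellipse membership and bounding boxes honor the rotation", {
  e <- Ellipse(c(0, 0), 2, 1, 90)   # major axis now vertical
  expect_true(pointInRegion(list(e), c(0, 1.9), "1"))
  expect_false(pointInRegion(list(e), c(1.9, 0), "1"))
  o <- regionAreasAndCentroids(list(e), 2e5, seed = 2)
  expect_lt(abs(o$areas[["1"]] - 2 * pi), 3 * mcAreaSE(o, "1"))
})
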