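test_that("region cardinalities enumerate exclusive membership", {
  card <- computeRegionCardinalities(list(A = c(1, 2, 3), B = c(3, 4)))
  expect_identical(regionCounts(card), c("1" = 2, "2" = 1, "12" = 1))

  card1 <- computeRegionCardinalities(list(A = c("x", "y")))
  expect_identical(regionCounts(card1), c("1" = 2))

  card3 <- computeRegionCardinalities(list(A = "1", B = "1", C = "1"))
  expect_equal(unname(regionCounts(card3)[["123"]]), 1)
  expect_equal(sum(regionCounts(card3)), 1)
})

test_that("duplicates within a set collapse and totals project correctly", {
  sc <- SetCollection(list(A = c("a", "a", "b"), B = c("b", "c")))
  expect_identical(members(sc)$A, c("a", "b"))
  card <- computeRegionCardinalities(sc)
  expect_identical(setTotals(card), c(A = 2, B = 2))
})

test_that("random fixtures match the brute-force tally exactly", {
  for (seed in 1:100) {
    n <- 1L + (seed %% 4L)
    sc <- generateRandomSets(n, universeSize = 50 + (seed * 3) %% 151,
                             membershipProb = 0.1 + 0.8 * (seed %% 7) / 7,
                             seed = seed)
    card <- computeRegionCardinalities(sc)
    expect_identical(regionCounts(card), bruteForceRegions(members(sc)))
    # conservation: regions partition the union
    expect_equal(sum(regionCounts(card)),
                 length(unique(unlist(members(sc)))))
    # projection: per-set sums recover set sizes
    expect_equal(unname(setTotals(card)),
                 unname(lengths(members(sc))))
  }
})

test_that("the fixture generator is seed-deterministic and respects bounds", {
  a <- generateRandomSets(2, 100, 0.5, seed = 7)
  b <- generateRandomSets(2, 100, 0.5, seed = 7)
  expect_identical(members(a), members(b))

  full <- generateRandomSets(3, 40, 1, seed = 1)
  card <- computeRegionCardinalities(full)
  expect_equal(unname(regionCounts(card)[["123"]]), 40)
  expect_equal(sum(regionCounts(card)), 40)

  empty <- generateRandomSets(2, 30, 0, seed = 1)
  expect_error(validateCardinalities(computeRegionCardinalities(empty)),
               class = "emptyDiagramError")

  expect_error(generateRandomSets(5, 10, 0.5, 1), class = "unsupportedSizeError")
  expect_error(generateRandomSets(2, 0, 0.5, 1), class = "invalidInputError")
  expect_error(generateRandomSets(2, 10, 1.5, 1), class = "invalidInputError")
})

test_that("direct cardinality input is zero-filled and validated", {
  card <- validateCardinalities(c("1" = 5, "12" = 2), nSets = 2)
  expect_identical(regionCounts(card), c("1" = 5, "2" = 0, "12" = 2))

  expect_error(validateCardinalities(c("1" = -1, "2" = 3)),
               class = "invalidInputError")
  expect_error(validateCardinalities(c("1" = 1), nSets = 5),
               class = "unsupportedSizeError")
  expect_error(validateCardinalities(c("1" = 0, "2" = 0)),
               class = "emptyDiagramError")
  expect_error(validateCardinalities(c("21" = 1)), class = "invalidInputError")
  expect_error(SetCollection(list(1:3)), class = "invalidInputError")
  expect_error(SetCollection(setNames(replicate(5, "x", simplify = FALSE),
                                      letters[1:5])),
               class = "unsupportedSizeError")
})
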