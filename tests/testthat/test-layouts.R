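test_that("canonical Venn layouts expose every region with positive area", {
  for (n in 1:4) {
    counts <- stats::setNames(rep(1, 2^n - 1), regionKeys(n))
    card <- validateCardinalities(counts, nSets = n)
    layout <- layoutVenn(card)
    expect_identical(diagramClass(layout), paste0("VENN_", n))
    o <- regionAreasAndCentroids(shapes(layout), 2e5, seed = 4)
    expect_true(all(o$areas > 0))
    expect_length(o$areas, 2^n - 1)
  }
  # one-set diagram: a single circle at the canvas center
  c1 <- shapes(layoutVenn(validateCardinalities(c("1" = 3))))[[1]]
  expect_equal(c1@center, c(0.5, 0.5))
})

test_that("scaled two-set regions are proportional to the counts", {
  card <- validateCardinalities(c("1" = 100, "2" = 70, "12" = 30))
  layout <- layoutScaledTwoSet(card)
  o <- regionAreasAndCentroids(shapes(layout), 1e6, seed = 8)
  frac <- o$areas / sum(o$areas)
  target <- c(100, 70, 30) / 200
  expect_true(all(abs(frac - target) / target < 0.02))
  # symmetric counts give equal radii
  sym <- layoutScaledTwoSet(validateCardinalities(c("1" = 35, "2" = 35, "12" = 30)))
  rr <- vapply(shapes(sym), function(s) s@radius, numeric(1))
  expect_equal(rr[1], rr[2])
})

test_that("degenerate scaled two-set counts give gapped tangency or concentric circles", {
  conc <- layoutScaledTwoSet(validateCardinalities(c("1" = 0, "2" = 0, "12" = 9)))
  sh <- shapes(conc)
  expect_equal(sh[[1]]@center, sh[[2]]@center, tolerance = 1e-9)
  expect_equal(sh[[1]]@radius, sh[[2]]@radius)

  disj <- layoutScaledTwoSet(validateCardinalities(c("1" = 50, "2" = 50, "12" = 0)))
  sh <- shapes(disj)
  d <- sqrt(sum((sh[[1]]@center - sh[[2]]@center)^2))
  expect_gt(d, sh[[1]]@radius + sh[[2]]@radius + 1e-6)   # visible gap

  incl <- layoutScaledTwoSet(validateCardinalities(c("1" = 80, "2" = 0, "12" = 20)))
  sh <- shapes(incl)
  d <- sqrt(sum((sh[[1]]@center - sh[[2]]@center)^2))
  expect_lt(d + sh[[2]]@radius, sh[[1]]@radius)          # strictly nested

  # an empty set keeps a visible minimum radius so its zero label has a home
  tiny <- layoutScaledTwoSet(validateCardinalities(c("1" = 500, "2" = 0, "12" = 0)))
  expect_gte(shapes(tiny)[[2]]@radius, 0.02)
})

test_that("scaling three- and four-set Venn diagrams is refused", {
  full3 <- validateCardinalities(stats::setNames(rep(2, 7), regionKeys(3)))
  expect_error(checkVennScaling(full3, TRUE), class = "unsupportedScalingError")
  expect_error(buildLayout(full3, fastStyle(scaled = TRUE)),
               class = "unsupportedScalingError")
  expect_true(checkVennScaling(full3, FALSE))

  two <- validateCardinalities(c("1" = 5, "2" = 5, "12" = 5))
  expect_true(checkVennScaling(two, TRUE))

  full4 <- validateCardinalities(stats::setNames(rep(1, 15), regionKeys(4)))
  expect_error(checkVennScaling(full4, TRUE), class = "unsupportedScalingError")
})

test_that("Euler layouts realize exactly the occupied regions", {
  cases <- list(
    EULER_2_INCLUSION = c("1" = 3, "2" = 0, "12" = 2),
    EULER_2_DISJOINT = c("1" = 3, "2" = 2, "12" = 0),
    EULER_3_DISJOINT = c("1" = 1, "2" = 2, "3" = 3),
    EULER_3_CHAIN = c("123" = 2, "23" = 3, "3" = 4),
    EULER_3_NESTED_DISJOINT = c("12" = 2, "2" = 3, "3" = 4),
    EULER_3_TWO_IN_ONE_DISJOINT = c("13" = 1, "23" = 2, "3" = 3),
    EULER_3_TWO_IN_ONE_OVERLAP = c("13" = 1, "23" = 2, "123" = 1, "3" = 3),
    EULER_3_PAIR_DISJOINT = c("1" = 1, "2" = 1, "12" = 1, "3" = 2),
    EULER_3_NESTED_IN_OVERLAP = c("12" = 1, "2" = 2, "23" = 1, "3" = 2),
    EULER_3_IN_INTERSECTION = c("123" = 1, "23" = 2, "2" = 2, "3" = 2),
    EULER_3_NO_EXCLUSIVE = c("2" = 1, "3" = 1, "12" = 1, "13" = 1,
                             "23" = 1, "123" = 1))
  for (cls in names(cases)) {
    n <- if (startsWith(cls, "EULER_2")) 2 else 3
    card <- validateCardinalities(cases[[cls]], nSets = n)
    expect_identical(classifyDiagram(card), cls)
    layout <- layoutEuler(card, cls)
    o <- regionAreasAndCentroids(shapes(layout), 2e5, seed = 6)
    occupied <- regionCounts(card) > 0
    expect_true(all(o$areas[occupied] > 0), label = paste(cls, "occupied"))
    expect_true(all(o$areas[!occupied] < 1e-3), label = paste(cls, "empty"))
  }
})

test_that("Euler layouts with collapsed free regions stay exact", {
  # equal sets: A = B = C, concentric equal circles
  eq <- validateCardinalities(c("123" = 5), nSets = 3)
  expect_identical(classifyDiagram(eq), "EULER_3_CHAIN")
  o <- regionAreasAndCentroids(shapes(layoutEuler(eq)), 2e5, seed = 6)
  expect_true(all(o$areas[setdiff(names(o$areas), "123")] < 1e-3))
  expect_gt(o$areas[["123"]], 0)

  # A = B, both inside C
  eq2 <- validateCardinalities(c("12" = 4, "3" = 3), nSets = 3)
  lay <- layoutEuler(eq2)
  o2 <- regionAreasAndCentroids(shapes(lay), 2e5, seed = 6)
  expect_true(all(o2$areas[c("1", "2", "13", "23", "123")] < 1e-3))
})

test_that("scaled Euler cases honor the set totals", {
  disj <- validateCardinalities(c("1" = 100, "2" = 25, "12" = 0))
  lay <- layoutEuler(disj, scaled = TRUE)
  rr <- vapply(shapes(lay), function(s) s@radius, numeric(1))
  expect_equal(rr[1] / rr[2], 2, tolerance = 1e-9)
  d <- sqrt(sum((shapes(lay)[[1]]@center - shapes(lay)[[2]]@center)^2))
  expect_gt(d, sum(rr))

  chain <- validateCardinalities(c("123" = 25, "23" = 75, "3" = 300), nSets = 3)
  lay2 <- layoutEuler(chain, scaled = TRUE)
  o <- regionAreasAndCentroids(shapes(lay2), 1e6, seed = 2)
  frac <- o$areas[c("123", "23", "3")] / sum(o$areas)
  expect_true(all(abs(frac - c(25, 75, 300) / 400) < 0.01))

  # a non-scalable case warns and falls back to template proportions
  two <- validateCardinalities(c("13" = 10, "23" = 20, "3" = 30), nSets = 3)
  expect_warning(layoutEuler(two, scaled = TRUE),
                 class = "unsupportedScalingWarning")
})

test_that("the Venn fallback always renders", {
  comprise <- validateCardinalities(c("13" = 3, "23" = 4), nSets = 3)
  layout <- buildLayout(comprise, fastStyle())
  expect_identical(diagramClass(layout), "FALLBACK_VENN_3")
  fig <- renderDiagram(layout, fastStyle())
  expect_s4_class(fig, "VennFigure")
  # zero labels are shown in Venn mode
  expect_length(layout@regionLabels, 7L)
})

test_that("layoutEuler refuses non-Euler classes and mismatched counts", {
  card <- validateCardinalities(c("1" = 1, "2" = 1, "12" = 1))
  expect_error(layoutEuler(card, "VENN_2"), class = "wrongClassError")
  chain <- validateCardinalities(c("123" = 2, "23" = 3, "3" = 4), nSets = 3)
  expect_error(layoutEuler(chain, "EULER_3_DISJOINT"), class = "wrongClassError")
})
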