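test_that("every two-set and three-set zero pattern maps to exactly one class", {
  all2 <- expand.grid(rep(list(c(FALSE, TRUE)), 3))
  for (r in seq_len(nrow(all2))) {
    card <- cardFromPattern(unlist(all2[r, ]), 2)
    cls <- classifyDiagram(card, eulerEnabled = TRUE)
    expect_length(cls, 1L)
    expect_true(cls %in% diagramClasses())
    expect_identical(classifyDiagram(card, eulerEnabled = FALSE), "VENN_2")
  }

  all3 <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  classes <- character(nrow(all3))
  for (r in seq_len(nrow(all3))) {
    card <- cardFromPattern(unlist(all3[r, ]), 3)
    cls <- classifyDiagram(card, eulerEnabled = TRUE)
    expect_length(cls, 1L)
    expect_true(cls %in% diagramClasses())
    classes[r] <- cls
    expect_identical(classifyDiagram(card, eulerEnabled = FALSE), "VENN_3")
  }
  expect_identical(nrow(all3), 128L)
  # the all-occupied pattern is the one and only standard three-set Venn
  expect_identical(sum(classes == "VENN_3"), 1L)
})

test_that("the documented two-set cases classify as printed", {
  full <- validateCardinalities(c("1" = 1, "2" = 1, "12" = 1))
  expect_identical(classifyDiagram(full), "VENN_2")

  incl <- validateCardinalities(c("1" = 3, "2" = 0, "12" = 2))
  expect_identical(classifyDiagram(incl), "EULER_2_INCLUSION")
  expect_identical(classifyDiagram(incl, eulerEnabled = FALSE), "VENN_2")

  disj <- validateCardinalities(c("1" = 3, "2" = 2, "12" = 0))
  expect_identical(classifyDiagram(disj), "EULER_2_DISJOINT")
})

test_that("three-set families are recognized in any set order", {
  # A inside B inside C
  chain <- validateCardinalities(c("123" = 2, "23" = 3, "3" = 4), nSets = 3)
  expect_identical(classifyDiagram(chain), "EULER_3_CHAIN")
  # same relation with permuted roles: C inside A inside B
  chain2 <- validateCardinalities(c("123" = 2, "12" = 3, "2" = 4), nSets = 3)
  expect_identical(classifyDiagram(chain2), "EULER_3_CHAIN")

  disj <- validateCardinalities(c("1" = 1, "2" = 2, "3" = 3), nSets = 3)
  expect_identical(classifyDiagram(disj), "EULER_3_DISJOINT")

  nd <- validateCardinalities(c("12" = 2, "2" = 3, "3" = 4), nSets = 3)
  expect_identical(classifyDiagram(nd), "EULER_3_NESTED_DISJOINT")

  two1 <- validateCardinalities(c("13" = 1, "23" = 2, "3" = 3), nSets = 3)
  expect_identical(classifyDiagram(two1), "EULER_3_TWO_IN_ONE_DISJOINT")

  two2 <- validateCardinalities(c("13" = 1, "23" = 2, "123" = 1, "3" = 3),
                                nSets = 3)
  expect_identical(classifyDiagram(two2), "EULER_3_TWO_IN_ONE_OVERLAP")

  pd <- validateCardinalities(c("1" = 1, "2" = 1, "12" = 1, "3" = 2), nSets = 3)
  expect_identical(classifyDiagram(pd), "EULER_3_PAIR_DISJOINT")

  nio <- validateCardinalities(c("12" = 1, "2" = 2, "23" = 1, "3" = 2), nSets = 3)
  expect_identical(classifyDiagram(nio), "EULER_3_NESTED_IN_OVERLAP")

  ii <- validateCardinalities(c("123" = 1, "23" = 2, "2" = 2, "3" = 2), nSets = 3)
  expect_identical(classifyDiagram(ii), "EULER_3_IN_INTERSECTION")

  ne <- validateCardinalities(c("2" = 1, "3" = 1, "12" = 1, "13" = 1,
                                "23" = 1, "123" = 1), nSets = 3)
  expect_identical(classifyDiagram(ne), "EULER_3_NO_EXCLUSIVE")
})

test_that("patterns without a circle realization fall back to Venn", {
  # two disjoint sets exactly comprising the third
  comprise <- validateCardinalities(c("13" = 3, "23" = 4), nSets = 3)
  expect_identical(classifyDiagram(comprise), "FALLBACK_VENN_3")
  # an empty set has no Euler drawing with three shapes
  emptyC <- validateCardinalities(c("1" = 1, "2" = 1, "12" = 1), nSets = 3)
  expect_identical(classifyDiagram(emptyC), "FALLBACK_VENN_3")
})

test_that("one- and four-set inputs always yield their Venn class", {
  one <- validateCardinalities(c("1" = 9))
  expect_identical(classifyDiagram(one), "VENN_1")
  z <- stats::setNames(rep(0, 15), regionKeys(4))
  z[c("1", "14", "1234")] <- c(4, 2, 1)
  four <- validateCardinalities(z, nSets = 4)
  expect_identical(classifyDiagram(four), "VENN_4")
})
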