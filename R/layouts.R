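#' @include classify.R transforms.R
NULL

## ---------------------------------------------------------------------------
## Canonical (unscaled) arrangements.  The constants are display conventions,
## chosen so that every region of the n-set diagram is non-degenerate; they
## are validated by the Monte-Carlo oracle, not by exact coordinates.

.vennConstants <- list(
  venn1 = list(center = c(0.5, 0.5), radius = 0.30),
  venn2 = list(radius = 0.30, centers = rbind(c(0.38, 0.5), c(0.62, 0.5))),
  venn3 = list(radius = 0.28, side = 0.25,
               angles = c(150, 30, 270)),     # set 1 upper-left, 2 upper-right, 3 bottom
  venn4 = list(semiMajor = 0.35, semiMinor = 0.20,
               centers = rbind(c(0.35, 0.47), c(0.47, 0.57),
                               c(0.53, 0.57), c(0.65, 0.47)),
               angles = c(-40, -40, 40, 40)))

#' Canonical Venn layout for 1 to 4 sets
#'
#' Produces the standard unscaled arrangement: a single circle; two equal
#' overlapping circles; three equal circles centered on an equilateral
#' triangle; or four ellipses in the classic symmetric arrangement.  All
#' `2^n - 1` regions have positive area by construction, so every count —
#' including zeros — can be displayed.
#'
#' @param card A validated [RegionCardinalities-class].
#' @return An unlabeled [VennLayout-class] with class `VENN_n` (or
#'   `FALLBACK_VENN_3` preserved when given via `fallback`).
#' @param fallback Mark the layout as the Venn fallback of an undrawable
#'   three-set Euler pattern.
#' @export
layoutVenn <- function(card, fallback = FALSE) {
  stopifnot(is(card, "RegionCardinalities"))
  n <- card@nSets
  k <- .vennConstants
  shapes <- switch(n,
    list(Circle(k$venn1$center, k$venn1$radius)),
    lapply(1:2, function(i) Circle(k$venn2$centers[i, ], k$venn2$radius)),
    {
      circum <- k$venn3$side / sqrt(3)
      lapply(1:3, function(i) {
        th <- k$venn3$angles[i] * pi / 180
        Circle(c(0.5, 0.5) + circum * c(cos(th), sin(th)), k$venn3$radius)
      })
    },
    lapply(1:4, function(i) Ellipse(k$venn4$centers[i, ], k$venn4$semiMajor,
                                    k$venn4$semiMinor, k$venn4$angles[i])))
  cls <- if (fallback && n == 3L) "FALLBACK_VENN_3" else .vennClass(n)
  .newLayout(shapes, cls, card@setLabels)
}

## ---------------------------------------------------------------------------
## Area-proportional two-set layout

#' Area-proportional two-set layout
#'
#' Radii are proportional to the square root of the set totals (counts are
#' used directly as areas) and the center distance is solved from the
#' intersection count by inverting the lens-area function, so the drawn
#' region areas are exactly proportional to the counts.  Degenerate counts
#' produce tangency — internal for total inclusion, external for disjoint
#' sets — opened up by a small visible gap; an empty set is drawn at the
#' configured minimum radius so its zero label remains placeable.
#'
#' @param card A validated two-set [RegionCardinalities-class].
#' @param tangencyGap Visible boundary gap at degenerate tangencies, canvas
#'   units (default 0.01).
#' @param minRadius Minimum drawn radius, canvas units (default 0.02).
#' @param margin Canvas margin fraction (default 0.05).
#' @param euler Euler mode: the layout is identical, only downstream labeling
#'   of zero regions differs.
#' @return An unlabeled [VennLayout-class].
#' @export
layoutScaledTwoSet <- function(card, tangencyGap = 0.01, minRadius = 0.02,
                               margin = 0.05, euler = FALSE) {
  stopifnot(is(card, "RegionCardinalities"), card@nSets == 2L)
  tot <- unname(setTotals(card))
  if (all(tot == 0))
    .vfError("emptyDiagramError", "both set totals are zero")
  inter <- card@counts[["12"]]
  ## an empty set keeps a token area so a visible minimum-radius circle remains
  eff <- pmax(tot, 1e-6 * max(tot))
  r <- radiusFromArea(eff)
  build <- function(gapAbs) {
    d <- if (inter <= 0) r[1] + r[2] + gapAbs
    else if (inter >= min(tot[tot > 0])) max(0, abs(r[1] - r[2]) - gapAbs)
    else solveDistance(r[1], r[2], inter)
    list(Circle(c(0, 0), r[1]), Circle(c(d, 0), r[2]))
  }
  ## two-pass fit so the gap is expressed in canvas units
  pre <- .fitToCanvas(build(0), margin)
  fit <- .fitToCanvas(build(tangencyGap / pre$scale), margin)
  shapes <- .applyMinRadius(fit$shapes, minRadius)
  cls <- if (!euler) "VENN_2" else .classify2(card@counts > 0)$class
  .newLayout(shapes, cls, card@setLabels)
}

#' Guard against unsupported area-proportional Venn requests
#'
#' In a three-circle system the pairwise intersection areas already determine
#' the triangle of centers, leaving no freedom to honor the triple
#' intersection — the drawn triple region is unchanged even if the true triple
#' intersection is zero.  Area-proportional three-set (and four-set) Venn
#' diagrams are therefore refused; callers may retry unscaled.
#'
#' @param card A validated [RegionCardinalities-class].
#' @param scaled Was scaling requested?
#' @param diagramClass The class chosen by [classifyDiagram()]; only standard
#'   Venn classes with three or more sets are refused.
#' @return Invisibly TRUE when the request is acceptable; otherwise an
#'   `unsupportedScalingError` is raised.
#' @export
checkVennScaling <- function(card, scaled,
                             diagramClass = classifyDiagram(card)) {
  stopifnot(is(card, "RegionCardinalities"))
  if (isTRUE(scaled) && diagramClass %in% c("VENN_3", "FALLBACK_VENN_3", "VENN_4"))
    .vfError("unsupportedScalingError", paste(
      "area-proportional scaling of", card@nSets, "set Venn diagrams is not",
      "supported: circle geometry is fully determined by the pairwise",
      "intersections, so the triple overlap cannot be honored; retry unscaled"))
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Euler layouts
##
## Template constants (abstract units, fitted to the canvas afterwards).  The
## scalable subset — all-disjoint, nested chain, nested pair + disjoint third,
## and both two-set cases — has its geometry fully determined by the set
## totals and the inclusion/disjointness relations; all other cases use fixed
## template proportions (a scaled request falls back with a warning).

.scalableEulerClasses <- c("EULER_2_INCLUSION", "EULER_2_DISJOINT",
                           "EULER_3_DISJOINT", "EULER_3_CHAIN",
                           "EULER_3_NESTED_DISJOINT")

## nested placement: inner circle inside outer, pushed off-center (downward)
## to leave label room; dFrac of the slack |R - r|.
.nestOffset <- function(R, r, dFrac = 0.6) max(0, (R - r)) * dFrac

.eulerTemplate3 <- function(class, perm) {
  ## returns circles in role order (i, j, k) as abstract Circle list
  circ <- switch(class,
    EULER_3_DISJOINT = list(Circle(c(0, 0), 1), Circle(c(2.5, 0), 1),
                            Circle(c(5, 0), 1)),
    EULER_3_CHAIN = list(Circle(c(0, -0.45), 0.37), Circle(c(0, -0.19), 0.68),
                         Circle(c(0, 0), 1)),
    EULER_3_NESTED_DISJOINT = list(Circle(c(0, -0.27), 0.55),
                                   Circle(c(0, 0), 1), Circle(c(2.3, 0), 0.8)),
    EULER_3_TWO_IN_ONE_DISJOINT = list(Circle(c(-0.5, 0), 0.42),
                                       Circle(c(0.5, 0), 0.42),
                                       Circle(c(0, 0), 1)),
    EULER_3_TWO_IN_ONE_OVERLAP = list(Circle(c(-0.32, 0), 0.5),
                                      Circle(c(0.32, 0), 0.5),
                                      Circle(c(0, 0), 1)),
    EULER_3_PAIR_DISJOINT = list(Circle(c(0, 0), 1), Circle(c(1.2, 0), 1),
                                 Circle(c(3.7, 0), 0.8)),
    EULER_3_NESTED_IN_OVERLAP = list(Circle(c(-0.45, 0), 0.35),
                                     Circle(c(0, 0), 1), Circle(c(1.4, 0), 1)),
    EULER_3_IN_INTERSECTION = list(Circle(c(0.5, 0), 0.2), Circle(c(0, 0), 1),
                                   Circle(c(1, 0), 1)),
    EULER_3_NO_EXCLUSIVE = list(Circle(c(0.5, 0), 0.55), Circle(c(0, 0), 1),
                                Circle(c(1, 0), 1)),
    .vfError("wrongClassError", paste("no three-set Euler template for", class)))
  circ
}

## degenerate-aware template adjustments: when a "free" region of the pattern
## is zero the template collapses the corresponding slack (equal radii,
## concentric placement) so the oracle sees zero area exactly where the count
## is zero.
.adjustTemplate3 <- function(class, circ, nzRole) {
  ## nzRole: named logical over role-relative keys "i","j","k","ij","ik","jk","ijk"
  if (class == "EULER_3_CHAIN") {
    if (!nzRole[["k"]])  { circ[[3]] <- Circle(circ[[2]]@center, circ[[2]]@radius) }
    if (!nzRole[["jk"]]) { circ[[2]] <- Circle(circ[[1]]@center, circ[[1]]@radius) }
    if (!nzRole[["k"]] && !nzRole[["jk"]])
      circ[[3]] <- Circle(circ[[1]]@center, circ[[1]]@radius)
  } else if (class == "EULER_3_NESTED_DISJOINT") {
    if (!nzRole[["j"]]) circ[[2]] <- Circle(circ[[1]]@center, circ[[1]]@radius)
  }
  circ
}

.roleKeys <- function(perm) {
  i <- perm[1]; j <- perm[2]; k <- perm[3]
  c(i = .k(i), j = .k(j), k = .k(k), ij = .k(i, j), ik = .k(i, k),
    jk = .k(j, k), ijk = .k(i, j, k))
}

#' Euler layout for a classified two- or three-set case
#'
#' Builds the case's arrangement: nested circles for inclusions, separated
#' circles for disjoint sets, and combinations thereof.  When `scaled = TRUE`
#' and the case belongs to the scalable subset (cases whose geometry is fully
#' determined by the set totals and the inclusion/disjointness relations —
#' no partial two-way overlap anywhere), radii are proportional to the square
#' root of the set totals and nesting offsets/gaps derive from the lens-area
#' inversion; otherwise fixed template proportions are used and a scaled
#' request falls back with a warning.
#'
#' @param card A validated [RegionCardinalities-class] (n = 2 or 3).
#' @param class The Euler case from [classifyDiagram()].
#' @param scaled Request area-proportional geometry (default FALSE).
#' @param tangencyGap,minRadius,margin See [layoutScaledTwoSet()].
#' @return An unlabeled [VennLayout-class].
#' @export
layoutEuler <- function(card, class = classifyDiagram(card), scaled = FALSE,
                        tangencyGap = 0.01, minRadius = 0.02, margin = 0.05) {
  stopifnot(is(card, "RegionCardinalities"))
  if (!startsWith(class, "EULER_"))
    .vfError("wrongClassError", paste(class, "is not an Euler case"))
  if (scaled && !(class %in% .scalableEulerClasses)) {
    .vfWarn("unsupportedScalingWarning", paste(
      "Euler case", class, "is not in the scalable subset;",
      "using template proportions"))
    scaled <- FALSE
  }
  n <- card@nSets
  if (n == 2L) {
    if (scaled) return(layoutScaledTwoSet(card, tangencyGap, minRadius,
                                          margin, euler = TRUE))
    shapes <- if (class == "EULER_2_DISJOINT")
      list(Circle(c(0, 0), 1), Circle(c(2.5, 0), 1))
    else {
      inner <- .classify2(card@counts > 0)$inner
      outerOnly <- card@counts[[.k(setdiff(1:2, inner))]]
      rIn <- if (outerOnly > 0) 0.55 else 1
      sh <- list(Circle(c(0, -.nestOffset(1, rIn)), rIn), Circle(c(0, 0), 1))
      if (inner == 1L) sh else rev(sh)
    }
    fit <- .fitToCanvas(shapes, margin)
    return(.newLayout(fit$shapes, class, card@setLabels))
  }
  ## three sets
  info <- .classify3(card@counts > 0)
  if (info$class != class)
    .vfError("wrongClassError", sprintf(
      "counts classify as %s, not %s", info$class, class))
  perm <- info$perm
  rk <- .roleKeys(perm)
  nzRole <- stats::setNames((card@counts > 0)[rk], names(rk))
  if (scaled) {
    roles <- .scaledEuler3(class, card, perm, tangencyGap, margin)
  } else {
    roles <- .adjustTemplate3(class, .eulerTemplate3(class, perm), nzRole)
    roles <- .fitToCanvas(roles, margin)$shapes
  }
  shapes <- vector("list", 3L)
  shapes[perm] <- roles          # back to set order
  .newLayout(shapes, class, card@setLabels)
}

## scaled geometry for the scalable three-set cases
.scaledEuler3 <- function(class, card, perm, tangencyGap, margin) {
  tot <- unname(setTotals(card))[perm]    # totals in role order (i, j, k)
  r <- radiusFromArea(pmax(tot, 1e-6 * max(tot)))
  build <- function(g) {
    switch(class,
      EULER_3_DISJOINT = {
        x2 <- r[1] + g + r[2]
        x3 <- x2 + r[2] + g + r[3]
        list(Circle(c(0, 0), r[1]), Circle(c(x2, 0), r[2]), Circle(c(x3, 0), r[3]))
      },
      EULER_3_CHAIN = {
        djk <- max(0, solveDistance(r[3], r[2], pi * r[2]^2) - g)
        dij <- max(0, solveDistance(r[2], r[1], pi * r[1]^2) - g)
        list(Circle(c(0, -djk - dij), r[1]), Circle(c(0, -djk), r[2]),
             Circle(c(0, 0), r[3]))
      },
      EULER_3_NESTED_DISJOINT = {
        dij <- max(0, solveDistance(r[2], r[1], pi * r[1]^2) - g)
        list(Circle(c(0, -dij), r[1]), Circle(c(0, 0), r[2]),
             Circle(c(r[2] + g + r[3], 0), r[3]))
      },
      .vfError("wrongClassError", paste(class, "is not scalable")))
  }
  pre <- .fitToCanvas(build(0), margin)
  .fitToCanvas(build(tangencyGap / pre$scale), margin)$shapes
}
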