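#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Closed-form circle geometry
##
## A set drawn as a circle has area A = pi r^2.  For two circles the
## intersection ("lens") area is a closed, strictly monotone function of the
## center distance, so a target intersection area determines the distance
## uniquely — the fact that makes two-set diagrams exactly scalable.  For
## three circles the three pairwise distances fix a unique triangle of
## centers, with no remaining freedom to honor the triple intersection.

#' Radius of the circle with a given area
#'
#' @param area Positive area.
#' @return `sqrt(area / pi)`.
#' @examples
#' radiusFromArea(pi)      # 1
#' radiusFromArea(4 * pi)  # 2
#' @export
radiusFromArea <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0))
    .vfError("invalidInputError", "area must be positive and finite")
  sqrt(area / pi)
}

#' Area of the intersection of two circles (the lens)
#'
#' For center distance `d` and radii `r1`, `r2` the overlap area is
#' \deqn{r_1^2 \cos^{-1}\frac{d^2+r_1^2-r_2^2}{2 d r_1} +
#'       r_2^2 \cos^{-1}\frac{d^2+r_2^2-r_1^2}{2 d r_2} -
#'       \tfrac12\sqrt{(-d+r_1+r_2)(d+r_1-r_2)(d-r_1+r_2)(d+r_1+r_2)}}
#' when the boundaries cross (`|r1 - r2| < d < r1 + r2`); the full area of the
#' smaller circle when one contains the other (`d <= |r1 - r2|`); and 0 when
#' the circles are disjoint (`d >= r1 + r2`).  Vectorized over `d`.
#'
#' @param d Non-negative center distance(s).
#' @param r1,r2 Positive radii.
#' @return Lens area(s), in squared length units.
#' @examples
#' lensArea(0, 1, 1)  # pi (coincident)
#' lensArea(2, 1, 1)  # 0  (tangent)
#' lensArea(1, 1, 1)  # 2*pi/3 - sqrt(3)/2
#' @export
lensArea <- function(d, r1, r2) {
  if (any(d < 0) || r1 <= 0 || r2 <= 0)
    .vfError("invalidInputError", "require d >= 0 and positive radii")
  out <- numeric(length(d))
  inc <- d <= abs(r1 - r2)          # one circle inside the other
  dis <- d >= r1 + r2               # disjoint
  mid <- !inc & !dis
  out[inc] <- pi * min(r1, r2)^2
  if (any(mid)) {
    dm <- d[mid]
    a1 <- r1^2 * acos(pmin(1, pmax(-1, (dm^2 + r1^2 - r2^2) / (2 * dm * r1))))
    a2 <- r2^2 * acos(pmin(1, pmax(-1, (dm^2 + r2^2 - r1^2) / (2 * dm * r2))))
    s <- pmax(0, (-dm + r1 + r2) * (dm + r1 - r2) * (dm - r1 + r2) * (dm + r1 + r2))
    out[mid] <- a1 + a2 - 0.5 * sqrt(s)
  }
  out
}

#' Center distance realizing a target intersection area
#'
#' Inverts [lensArea()] in its strictly decreasing argument by bisection on
#' `[|r1 - r2|, r1 + r2]`.  A target of 0 returns external tangency
#' (`r1 + r2`); a target equal to the smaller circle's full area returns
#' internal tangency (`|r1 - r2|`).
#'
#' @param r1,r2 Positive radii.
#' @param target Desired lens area, in `[0, pi * min(r1, r2)^2]`.
#' @param tol Absolute tolerance on the achieved area (default `1e-9`).
#' @param maxIter Bisection iteration cap (default 200).
#' @return The center distance `d` with `|lensArea(d, r1, r2) - target| <= tol`.
#' @examples
#' solveDistance(1, 1, pi) # 0
#' solveDistance(1, 1, 0)  # 2
#' @export
solveDistance <- function(r1, r2, target, tol = 1e-9, maxIter = 200L) {
  if (r1 <= 0 || r2 <= 0)
    .vfError("invalidInputError", "radii must be positive")
  if (length(tol) != 1L || tol <= 0)
    .vfError("invalidInputError", "tol must be a positive number")
  amax <- pi * min(r1, r2)^2
  if (target < 0 || target > amax + 1e-12 * amax)
    .vfError("infeasibleOverlapError", sprintf(
      "target intersection area %.6g outside [0, %.6g] feasible for radii (%.4g, %.4g)",
      target, amax, r1, r2))
  if (target == 0) return(r1 + r2)
  if (target >= amax) return(abs(r1 - r2))
  lo <- abs(r1 - r2)   # lensArea(lo) = amax >= target
  hi <- r1 + r2        # lensArea(hi) = 0 <= target
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    a <- lensArea(mid, r1, r2)
    if (abs(a - target) <= tol) return(mid)
    if (a > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Place three circles from set areas and pairwise intersection areas
#'
#' Solves the three center distances with [solveDistance()] and builds the
#' unique triangle of centers: circle A at the origin, B on the positive
#' x-axis, C in the upper half-plane.  The triple intersection does not enter
#' the construction — the pairwise distances already determine the whole
#' figure, which is exactly why three-set circle diagrams cannot be
#' area-proportional in the triple region.
#'
#' @param rA,rB,rC Positive radii.
#' @param areaAB,areaBC,areaAC Pairwise intersection areas (each feasible for
#'   its circle pair).
#' @param gap Center-to-center clearance factor used only when all three
#'   pairwise areas are zero, where a disjoint row with visible gaps
#'   (`gap * max radius` between boundaries) is returned instead.
#' @return A [ThreeCircleArrangement-class].
#' @export
placeThreeCircles <- function(rA, rB, rC, areaAB, areaBC, areaAC, gap = 0.25) {
  if (any(c(rA, rB, rC) <= 0))
    .vfError("invalidInputError", "radii must be positive")
  if (areaAB == 0 && areaBC == 0 && areaAC == 0) {
    g <- gap * max(rA, rB, rC)
    cA <- c(0, 0)
    cB <- c(rA + g + rB, 0)
    cC <- c(cB[1] + rB + g + rC, 0)
    return(new("ThreeCircleArrangement",
               circles = list(Circle(cA, rA), Circle(cB, rB), Circle(cC, rC)),
               dAB = cB[1], dBC = cC[1] - cB[1], dAC = cC[1]))
  }
  dAB <- solveDistance(rA, rB, areaAB)
  dBC <- solveDistance(rB, rC, areaBC)
  dAC <- solveDistance(rA, rC, areaAC)
  eps <- 1e-9 * max(dAB, dBC, dAC)
  if (dAB > dBC + dAC + eps || dBC > dAB + dAC + eps || dAC > dAB + dBC + eps)
    .vfError("unrealizableArrangementError", sprintf(
      paste("solved distances dAB = %.4g, dBC = %.4g, dAC = %.4g violate the",
            "triangle inequality; no circle arrangement realizes these",
            "pairwise intersection areas"), dAB, dBC, dAC))
  cA <- c(0, 0)
  cB <- c(dAB, 0)
  if (dAB < 1e-12) {
    cC <- c(dAC, 0)   # A and B concentric; C anywhere at distance dAC
  } else {
    x <- (dAB^2 + dAC^2 - dBC^2) / (2 * dAB)
    y2 <- dAC^2 - x^2
    cC <- c(x, sqrt(max(0, y2)))
  }
  d <- function(p, q) sqrt(sum((p - q)^2))
  new("ThreeCircleArrangement",
      circles = list(Circle(cA, rA), Circle(cB, rB), Circle(cC, rC)),
      dAB = d(cA, cB), dBC = d(cB, cC), dAC = d(cA, cC))
}

## ---------------------------------------------------------------------------
## Point membership and bounding boxes (vectorized over points)

setGeneric(".containsPoints", function(shape, x, y) standardGeneric(".containsPoints"))

setMethod(".containsPoints", "Circle", function(shape, x, y) {
  (x - shape@center[1])^2 + (y - shape@center[2])^2 <= shape@radius^2
})

setMethod(".containsPoints", "Ellipse", function(shape, x, y) {
  th <- shape@angle * pi / 180
  dx <- x - shape@center[1]
  dy <- y - shape@center[2]
  u <- dx * cos(th) + dy * sin(th)     # into the ellipse frame
  v <- -dx * sin(th) + dy * cos(th)
  (u / shape@semiMajor)^2 + (v / shape@semiMinor)^2 <= 1
})

setGeneric(".shapeBBox", function(shape) standardGeneric(".shapeBBox"))

setMethod(".shapeBBox", "Circle", function(shape) {
  c(xmin = shape@center[1] - shape@radius, xmax = shape@center[1] + shape@radius,
    ymin = shape@center[2] - shape@radius, ymax = shape@center[2] + shape@radius)
})

setMethod(".shapeBBox", "Ellipse", function(shape) {
  th <- shape@angle * pi / 180
  ex <- sqrt((shape@semiMajor * cos(th))^2 + (shape@semiMinor * sin(th))^2)
  ey <- sqrt((shape@semiMajor * sin(th))^2 + (shape@semiMinor * cos(th))^2)
  c(xmin = shape@center[1] - ex, xmax = shape@center[1] + ex,
    ymin = shape@center[2] - ey, ymax = shape@center[2] + ey)
})

#' Is a point inside a region of a shape arrangement?
#'
#' @param shapes List of [Circle-class]/[Ellipse-class].
#' @param point Numeric (x, y).
#' @param regionKey Canonical region key (e.g. "13"): the point must be inside
#'   exactly the shapes with those indices.
#' @return Logical scalar.
#' @export
pointInRegion <- function(shapes, point, regionKey) {
  inside <- vapply(shapes, function(s)
    .containsPoints(s, point[1], point[2]), logical(1))
  identical(which(inside), as.integer(.keyIndices(regionKey)))
}

## ---------------------------------------------------------------------------
## Monte-Carlo region oracle

#' Monte-Carlo region areas and centroids
#'
#' Uniform rejection sampling over the joint bounding box of the shapes: each
#' sample is assigned to the region keyed by the subset of shapes containing
#' it; a region's area is the box area times its hit fraction and its centroid
#' is the mean of its hits.  This is the single source of truth for
#' ellipse-region areas and for all label anchor points; it is deterministic
#' for a fixed seed and leaves the caller's RNG state untouched.
#'
#' @param shapes Non-empty list of [Circle-class]/[Ellipse-class] (up to 4).
#' @param nSamples Number of samples (>= 1e4; default 1e6).
#' @param seed Integer seed (default 20110126).
#' @return List with `areas` (named numeric over all `2^n - 1` region keys),
#'   `centroids` (named list; `NULL` for regions with no hits), `hits` (named
#'   integer hit counts), `boxArea`, and `nSamples`.
#' @examples
#' o <- regionAreasAndCentroids(list(Circle(c(0, 0), 1)), nSamples = 1e5)
#' o$areas  # close to pi
#' @export
regionAreasAndCentroids <- function(shapes, nSamples = 1e6, seed = 20110126) {
  if (!is.list(shapes) || length(shapes) < 1L || length(shapes) > 4L ||
      !all(vapply(shapes, is, logical(1), "DiagramShape")))
    .vfError("invalidInputError", "shapes must be a list of 1 to 4 Circle/Ellipse")
  if (nSamples < 1e4)
    .vfError("invalidInputError", "nSamples must be at least 1e4")
  nSamples <- as.integer(nSamples)
  n <- length(shapes)
  bbs <- vapply(shapes, .shapeBBox, numeric(4))
  box <- c(xmin = min(bbs["xmin", ]), xmax = max(bbs["xmax", ]),
           ymin = min(bbs["ymin", ]), ymax = max(bbs["ymax", ]))
  boxArea <- (box["xmax"] - box["xmin"]) * (box["ymax"] - box["ymin"])
  pts <- .withSeed(seed, list(
    x = stats::runif(nSamples, box["xmin"], box["xmax"]),
    y = stats::runif(nSamples, box["ymin"], box["ymax"])))
  id <- integer(nSamples)
  for (i in seq_len(n))
    id <- id + bitwShiftL(1L, i - 1L) * .containsPoints(shapes[[i]], pts$x, pts$y)
  keys <- regionKeys(n)
  ids <- vapply(keys, function(k)
    sum(bitwShiftL(1L, .keyIndices(k) - 1L)), numeric(1))
  hits <- stats::setNames(tabulate(match(id, ids), nbins = length(keys)), keys)
  areas <- unname(boxArea) * hits / nSamples
  centroids <- stats::setNames(vector("list", length(keys)), keys)
  for (k in which(hits > 0L)) {
    sel <- id == ids[k]
    centroids[[k]] <- c(mean(pts$x[sel]), mean(pts$y[sel]))
  }
  list(areas = areas, centroids = centroids, hits = hits,
       boxArea = unname(boxArea), nSamples = nSamples)
}
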