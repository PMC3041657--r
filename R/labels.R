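#' @include layouts.R
NULL

## membership id of grid/sample points for a region key
.regionId <- function(key) sum(bitwShiftL(1L, .keyIndices(key) - 1L))

## Deterministic anchor search: grid points inside the region, preferring the
## one closest to the Monte-Carlo centroid (the centroid itself can fall
## outside non-convex regions such as crescents).
.regionAnchor <- function(shapes, key, centroid, gridN = 201L) {
  if (!is.null(centroid) && pointInRegion(shapes, centroid, key))
    return(centroid)
  bb <- .shapesBBox(shapes)
  gx <- seq(bb["xmin"], bb["xmax"], length.out = gridN)
  gy <- seq(bb["ymin"], bb["ymax"], length.out = gridN)
  pts <- expand.grid(x = gx, y = gy)
  id <- integer(nrow(pts))
  for (i in seq_along(shapes))
    id <- id + bitwShiftL(1L, i - 1L) * .containsPoints(shapes[[i]], pts$x, pts$y)
  sel <- id == .regionId(key)
  if (!any(sel)) return(NULL)
  px <- pts$x[sel]; py <- pts$y[sel]
  ref <- if (is.null(centroid)) c(mean(px), mean(py)) else centroid
  best <- which.min((px - ref[1])^2 + (py - ref[2])^2)
  c(px[best], py[best])
}

## fallback anchor for a region with (numerically) zero drawn area — only
## zero-count regions in degenerate scaled Venn layouts reach this.
.degenerateAnchor <- function(shapes, key) {
  idx <- .keyIndices(key)
  ctrs <- lapply(shapes[idx], function(s) s@center)
  if (length(idx) >= 2L) {
    Reduce(`+`, ctrs) / length(ctrs)
  } else {
    s <- shapes[[idx]]
    ext <- if (is(s, "Circle")) s@radius else .shapeBBox(s)[["ymax"]] - s@center[2]
    s@center + c(0, ext + 0.04 + 0.02 * (idx - 1L))
  }
}

## boundary extent of a shape along unit direction u (from the center)
.extentAlong <- function(shape, u) {
  if (is(shape, "Circle")) return(shape@radius)
  th <- shape@angle * pi / 180
  ca <- u[1] * cos(th) + u[2] * sin(th)    # direction in ellipse frame
  sa <- -u[1] * sin(th) + u[2] * cos(th)
  a <- shape@semiMajor; b <- shape@semiMinor
  (a * b) / sqrt((b * ca)^2 + (a * sa)^2)
}

#' Attach area labels, captions and leader lines to a layout
#'
#' Numeric area labels are anchored at the Monte-Carlo centroid of each drawn
#' region (with a deterministic in-region fallback for non-convex regions);
#' in Venn mode every region is labeled, zeros included, while Euler mode
#' labels only the occupied regions.  Captions are placed outside each shape
#' away from the diagram center ("default"), attached beneath the set's
#' exclusive-region label ("text"), or at user coordinates ("explicit").  In
#' area-proportional two-set layouts an intersection lens narrower than the
#' small-region threshold has its label pulled above the shapes and connected
#' by a leader line.
#'
#' @param layout An unlabeled [VennLayout-class] (already transformed).
#' @param card The [RegionCardinalities-class] the layout was built from.
#' @param style A [DiagramStyle-class]; uses the caption mode/distance, the
#'   small-region threshold and the oracle sample count and seed.
#' @return The [VennLayout-class] with `regionAnchors`, `regionLabels`,
#'   `captionAnchors` and `leaderLines` filled in.
#' @export
attachLabels <- function(layout, card, style = DiagramStyle()) {
  stopifnot(is(layout, "VennLayout"), is(card, "RegionCardinalities"),
            length(layout@shapes) == card@nSets)
  shapes <- layout@shapes
  cls <- layout@diagramClass
  vennMode <- !startsWith(cls, "EULER_")
  keys <- names(card@counts)
  labeled <- if (vennMode) keys else keys[card@counts > 0]
  oracle <- regionAreasAndCentroids(shapes, nSamples = style@samples,
                                    seed = style@oracleSeed)
  anchors <- list()
  for (key in labeled) {
    a <- .regionAnchor(shapes, key, oracle$centroids[[key]])
    if (is.null(a)) a <- .degenerateAnchor(shapes, key)
    anchors[[key]] <- a
  }
  labels <- stats::setNames(
    vapply(labeled, function(k) format(card@counts[[k]], scientific = FALSE),
           character(1)), labeled)
  ## leader line for a too-narrow two-set lens
  leaders <- list()
  if (card@nSets == 2L && card@counts[["12"]] > 0 &&
      all(vapply(shapes, is, logical(1), "Circle"))) {
    c1 <- shapes[[1]]; c2 <- shapes[[2]]
    d <- sqrt(sum((c1@center - c2@center)^2))
    lensWidth <- c1@radius + c2@radius - d
    if (d > abs(c1@radius - c2@radius) && lensWidth > 0 &&
        lensWidth < style@smallRegionThreshold) {
      u <- (c2@center - c1@center) / d
      inside <- c1@center + u * (d + c1@radius - c2@radius) / 2
      top <- max(vapply(shapes, function(s) .shapeBBox(s)[["ymax"]], numeric(1)))
      outside <- c(inside[1], top + 0.05)
      leaders[[1]] <- list(from = inside, to = outside, region = "12")
      anchors[["12"]] <- inside
    }
  }
  ## captions
  dctr <- Reduce(`+`, lapply(shapes, function(s) s@center)) / length(shapes)
  capText <- if (length(style@captionText) == card@nSets) style@captionText
             else card@setLabels
  caps <- list()
  for (i in seq_len(card@nSets)) {
    s <- shapes[[i]]
    placed <- FALSE
    if (style@captionMode == "explicit" &&
        nrow(style@captionPositions) >= i) {
      pos <- style@captionPositions[i, ]
      just <- if (style@captionJust == "auto") "centre" else style@captionJust
      placed <- TRUE
    } else if (style@captionMode == "text") {
      exKey <- as.character(i)
      if (!is.null(anchors[[exKey]])) {
        pos <- anchors[[exKey]] - c(0, 1.4 * style@labelSize)
        just <- "centre"
        placed <- TRUE
      }
    }
    if (!placed) {
      u <- s@center - dctr
      nu <- sqrt(sum(u^2))
      u <- if (nu < 1e-9) c(0, 1) else u / nu
      pos <- s@center + u * (.extentAlong(s, u) + style@captionDistance)
      pos <- pmin(pmax(pos, 0.02), 0.98)
      just <- if (style@captionJust != "auto") style@captionJust
              else if (u[1] > 0.3) "left"
              else if (u[1] < -0.3) "right"
              else "centre"
    }
    caps[[capText[i]]] <- list(pos = unname(pos), just = just, text = capText[i])
  }
  layout@regionAnchors <- anchors
  layout@captionAnchors <- caps
  layout@leaderLines <- leaders
  attr(labels, "names") <- labeled
  layout@regionLabels <- labels
  layout
}
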