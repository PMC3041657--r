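#' @include geometry.R
NULL

## Rigid transforms of shapes, anchors and whole layouts.  The canvas is the
## unit square with y increasing upward; rotation is about its center
## (0.5, 0.5) and inversion is the reflection across the vertical axis
## through the center.  Inversion is applied before rotation.

.transformPoint <- function(p, rotationDeg = 0, invert = FALSE,
                            center = c(0.5, 0.5)) {
  q <- p - center
  if (invert) q[1] <- -q[1]
  th <- rotationDeg * pi / 180
  c(q[1] * cos(th) - q[2] * sin(th),
    q[1] * sin(th) + q[2] * cos(th)) + center
}

setGeneric(".transformShape", function(shape, rotationDeg, invert, center)
  standardGeneric(".transformShape"))

setMethod(".transformShape", "Circle", function(shape, rotationDeg, invert, center) {
  Circle(.transformPoint(shape@center, rotationDeg, invert, center), shape@radius)
})

setMethod(".transformShape", "Ellipse", function(shape, rotationDeg, invert, center) {
  ang <- shape@angle
  if (invert) ang <- 180 - ang      # reflection across a vertical axis
  ang <- ang + rotationDeg
  Ellipse(.transformPoint(shape@center, rotationDeg, invert, center),
          shape@semiMajor, shape@semiMinor, ang %% 360)
})

#' Rotate and/or mirror a layout
#'
#' Applies an inversion (reflection across the vertical axis through the
#' canvas center) followed by a counter-clockwise rotation about the canvas
#' center to every shape, region anchor, caption anchor and leader line of a
#' layout.  Region counts and label texts are untouched, so the operation is
#' an isometry of the drawn figure.
#'
#' @param layout A [VennLayout-class].
#' @param rotationDeg Rotation in degrees counter-clockwise (default 0).
#' @param invert Mirror the diagram first (default FALSE).
#' @return The transformed [VennLayout-class].
#' @export
transformLayout <- function(layout, rotationDeg = 0, invert = FALSE) {
  stopifnot(is(layout, "VennLayout"))
  if (rotationDeg == 0 && !invert) return(layout)
  ctr <- c(0.5, 0.5)
  tp <- function(p) .transformPoint(p, rotationDeg, invert, ctr)
  layout@shapes <- lapply(layout@shapes, .transformShape,
                          rotationDeg = rotationDeg, invert = invert,
                          center = ctr)
  layout@regionAnchors <- lapply(layout@regionAnchors, tp)
  layout@captionAnchors <- lapply(layout@captionAnchors, function(a) {
    a$pos <- tp(a$pos); a
  })
  layout@leaderLines <- lapply(layout@leaderLines, function(l) {
    l$from <- tp(l$from); l$to <- tp(l$to); l
  })
  layout
}

## ---------------------------------------------------------------------------
## Canvas fitting: layouts are built in convenient abstract units, then
## uniformly rescaled and centered into the margin-inset unit square.

.shapesBBox <- function(shapes) {
  bbs <- vapply(shapes, .shapeBBox, numeric(4))
  c(xmin = min(bbs["xmin", ]), xmax = max(bbs["xmax", ]),
    ymin = min(bbs["ymin", ]), ymax = max(bbs["ymax", ]))
}

## Returns list(shapes, scale, map) where map is the point mapping used.
.fitToCanvas <- function(shapes, margin = 0.05) {
  bb <- .shapesBBox(shapes)
  w <- bb["xmax"] - bb["xmin"]
  h <- bb["ymax"] - bb["ymin"]
  avail <- 1 - 2 * margin
  s <- avail / max(w, h)
  ctr <- c((bb["xmin"] + bb["xmax"]) / 2, (bb["ymin"] + bb["ymax"]) / 2)
  map <- function(p) unname(c(0.5, 0.5) + s * (p - ctr))
  out <- lapply(shapes, function(sh) {
    if (is(sh, "Circle")) Circle(map(sh@center), sh@radius * s)
    else Ellipse(map(sh@center), sh@semiMajor * s, sh@semiMinor * s, sh@angle)
  })
  list(shapes = out, scale = unname(s), map = map)
}

## Enforce a minimum drawn radius so zero labels remain placeable.
.applyMinRadius <- function(shapes, minRadius) {
  lapply(shapes, function(sh) {
    if (is(sh, "Circle") && sh@radius < minRadius) Circle(sh@center, minRadius)
    else sh
  })
}
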