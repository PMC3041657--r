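## Region keys --------------------------------------------------------------
##
## A region of an n-set diagram is the locus of elements belonging to exactly
## one non-empty subset of the sets.  Subsets are keyed by their sorted
## 1-based indices pasted together ("1", "13", "123", ...), giving 2^n - 1
## canonical keys.

#' All canonical region keys for an n-set diagram
#'
#' @param n Number of sets (1 to 4).
#' @return Character vector of the `2^n - 1` region keys, ordered by subset
#'   size then lexicographically ("1", "2", ..., "12", ..., "1234").
#' @examples
#' regionKeys(2) # "1" "2" "12"
#' @export
regionKeys <- function(n) {
  n <- .checkN(n)
  keys <- character(0)
  for (size in seq_len(n)) {
    combs <- utils::combn(n, size)
    keys <- c(keys, apply(combs, 2L, paste, collapse = ""))
  }
  keys
}

.checkN <- function(n) {
  if (length(n) != 1L || is.na(n) || n != as.integer(n))
    .vfError("invalidInputError", "number of sets must be a single integer")
  n <- as.integer(n)
  if (n < 1L || n > 4L)
    .vfError("unsupportedSizeError", sprintf(
      "diagrams support 1 to 4 sets, got %d", n))
  n
}

.keyIndices <- function(key) as.integer(strsplit(key, "")[[1L]])

## membership id (sum of 2^(i-1) over indices) -> canonical key
.keyFromId <- function(id, n) {
  idx <- which(bitwAnd(id, bitwShiftL(1L, 0:(n - 1L))) != 0L)
  paste(idx, collapse = "")
}

## SetCollection -------------------------------------------------------------

#' SetCollection: one to four named element sets
#'
#' Holds the input sets of a diagram: an ordered vector of distinct labels and,
#' for each label, a character vector of element identifiers.  Elements are
#' opaque tokens compared by exact string equality; duplicates within one set
#' are collapsed.
#'
#' @slot setLabels Character vector of distinct, non-empty set labels
#'   (length 1 to 4; the display order of the diagram).
#' @slot members List of character vectors, parallel to `setLabels`.
#' @seealso [SetCollection()] constructor, [computeRegionCardinalities()]
#' @exportClass SetCollection
setClass("SetCollection",
  representation(setLabels = "character", members = "list"))

setValidity("SetCollection", function(object) {
  n <- length(object@setLabels)
  if (n < 1L || n > 4L)
    return(sprintf("between 1 and 4 sets are supported, got %d", n))
  if (anyDuplicated(object@setLabels))
    return("set labels must be unique")
  if (any(!nzchar(object@setLabels)) || anyNA(object@setLabels))
    return("set labels must be non-empty strings")
  if (length(object@members) != n)
    return("members must be parallel to setLabels")
  for (m in object@members) {
    if (!is.character(m)) return("set members must be character vectors")
    if (anyDuplicated(m)) return("set members must be deduplicated")
  }
  TRUE
})

#' Construct a SetCollection
#'
#' @param sets Named list of vectors of element identifiers (coerced to
#'   character; duplicates within a set are dropped).
#' @return A [SetCollection-class] object.
#' @examples
#' SetCollection(list(A = c("x", "y", "z"), B = c("z", "w")))
#' @export
SetCollection <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    .vfError("invalidInputError", "sets must be a named list of element vectors")
  if (length(sets) > 4L)
    .vfError("unsupportedSizeError", sprintf(
      "diagrams support 1 to 4 sets, got %d", length(sets)))
  members <- lapply(sets, function(m) unique(as.character(m)))
  new("SetCollection", setLabels = names(sets), members = unname(members))
}

## RegionCardinalities -------------------------------------------------------

#' RegionCardinalities: the partial-area table of a diagram
#'
#' Stores, for every non-empty subset of the n sets, the number of elements
#' belonging to exactly that subset (the diagram's "partial areas").  All
#' `2^n - 1` keys are present; zeros are explicit.
#'
#' @slot nSets Integer, number of sets (1 to 4).
#' @slot counts Named numeric vector of non-negative integers; names are the
#'   canonical [regionKeys()].
#' @slot setLabels Character vector of display labels, one per set.
#' @seealso [computeRegionCardinalities()], [validateCardinalities()]
#' @exportClass RegionCardinalities
setClass("RegionCardinalities",
  representation(nSets = "integer", counts = "numeric", setLabels = "character"))

setValidity("RegionCardinalities", function(object) {
  n <- object@nSets
  if (length(n) != 1L || is.na(n) || n < 1L || n > 4L)
    return("nSets must be in 1..4")
  keys <- regionKeys(n)
  if (!identical(names(object@counts), keys))
    return("counts must carry exactly the canonical region keys, in order")
  if (anyNA(object@counts) || any(object@counts < 0))
    return("all region counts must be non-negative")
  if (any(object@counts != round(object@counts)))
    return("region counts must be whole numbers")
  if (length(object@setLabels) != n)
    return("setLabels must have one label per set")
  TRUE
})

## Geometric primitives ------------------------------------------------------

#' Virtual parent of the drawable shapes
#' @exportClass DiagramShape
setClass("DiagramShape", representation("VIRTUAL"))

#' Circle shape
#'
#' @slot center Numeric (x, y) in canvas units.
#' @slot radius Positive radius; the enclosed area is `pi * radius^2`.
#' @exportClass Circle
setClass("Circle", contains = "DiagramShape",
  representation(center = "numeric", radius = "numeric"))

setValidity("Circle", function(object) {
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    return("center must be two finite coordinates")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    return("radius must be a single positive finite number")
  TRUE
})

#' @rdname Circle-class
#' @param center Numeric (x, y).
#' @param radius Positive number.
#' @export
Circle <- function(center, radius) new("Circle", center = as.numeric(center),
                                       radius = as.numeric(radius))

#' Ellipse shape
#'
#' @slot center Numeric (x, y) in canvas units.
#' @slot semiMajor,semiMinor Positive semi-axes, `semiMajor >= semiMinor`.
#' @slot angle Rotation of the major axis, degrees counter-clockwise.
#' @exportClass Ellipse
setClass("Ellipse", contains = "DiagramShape",
  representation(center = "numeric", semiMajor = "numeric",
                 semiMinor = "numeric", angle = "numeric"))

setValidity("Ellipse", function(object) {
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    return("center must be two finite coordinates")
  if (object@semiMinor <= 0 || object@semiMajor < object@semiMinor)
    return("semi-axes must satisfy semiMajor >= semiMinor > 0")
  if (!is.finite(object@angle)) return("angle must be finite")
  TRUE
})

#' @rdname Ellipse-class
#' @param center Numeric (x, y).
#' @param semiMajor,semiMinor Positive semi-axes.
#' @param angle Degrees counter-clockwise.
#' @export
Ellipse <- function(center, semiMajor, semiMinor, angle = 0)
  new("Ellipse", center = as.numeric(center), semiMajor = as.numeric(semiMajor),
      semiMinor = as.numeric(semiMinor), angle = as.numeric(angle))

#' Three circles placed from pairwise center distances
#'
#' @slot circles List of three [Circle-class] objects (A, B, C).
#' @slot dAB,dBC,dAC The pairwise center distances used for the construction.
#' @exportClass ThreeCircleArrangement
setClass("ThreeCircleArrangement",
  representation(circles = "list", dAB = "numeric", dBC = "numeric",
                 dAC = "numeric"))

setValidity("ThreeCircleArrangement", function(object) {
  if (length(object@circles) != 3L ||
      !all(vapply(object@circles, is, logical(1), "Circle")))
    return("circles must be a list of three Circle objects")
  cc <- lapply(object@circles, function(s) s@center)
  d <- c(sqrt(sum((cc[[1]] - cc[[2]])^2)),
         sqrt(sum((cc[[2]] - cc[[3]])^2)),
         sqrt(sum((cc[[1]] - cc[[3]])^2)))
  if (max(abs(d - c(object@dAB, object@dBC, object@dAC))) > 1e-9)
    return("stored distances disagree with circle centers")
  TRUE
})

## Layout --------------------------------------------------------------------

#' VennLayout: positioned shapes, label anchors and leader lines
#'
#' The geometric output of the layout engine, in the unit-square canvas
#' (y increasing upward).  Region anchors exist for every region that carries
#' a printed numeric label; caption anchors name the sets.
#'
#' @slot shapes List of [Circle-class]/[Ellipse-class], one per set, in set order.
#' @slot diagramClass Character scalar, one of the values enumerated in
#'   [classifyDiagram()].
#' @slot regionAnchors Named list (region key -> numeric (x, y)).
#' @slot regionLabels Named character vector of printed area-label texts.
#' @slot captionAnchors Named list (set label -> list(pos = (x, y),
#'   just = grid justification)).
#' @slot leaderLines List of list(from = (x, y), to = (x, y), region = key).
#' @slot setLabels Character vector of set labels in shape order.
#' @exportClass VennLayout
setClass("VennLayout",
  representation(shapes = "list", diagramClass = "character",
                 regionAnchors = "list", regionLabels = "character",
                 captionAnchors = "list", leaderLines = "list",
                 setLabels = "character"))

setValidity("VennLayout", function(object) {
  if (!all(vapply(object@shapes, is, logical(1), "DiagramShape")))
    return("shapes must be Circle or Ellipse objects")
  if (length(object@diagramClass) != 1L)
    return("diagramClass must be a single string")
  TRUE
})

.newLayout <- function(shapes, diagramClass, setLabels)
  new("VennLayout", shapes = shapes, diagramClass = diagramClass,
      regionAnchors = list(), regionLabels = character(0),
      captionAnchors = list(), leaderLines = list(), setLabels = setLabels)

## Style ---------------------------------------------------------------------

#' DiagramStyle: the graphical parameter surface
#'
#' Four parameter groups (shape-fill, shape-line, labels, titles) plus layout
#' switches.  Construct with [DiagramStyle()] or parse from JSON with
#' [parseStyle()]; all fields have defaults chosen to give sensible diagrams
#' without customization.
#'
#' @slot fill Fill colors, recycled per shape.
#' @slot alpha Fill alpha in `[0, 1]`, recycled per shape.
#' @slot lineStyle Line types per shape: solid, dashed, dotted, dotdash,
#'   longdash, twodash or blank.
#' @slot lineWidth,lineColor Shape boundary width (pt) and colors.
#' @slot labelFontFamily,labelFontFace,labelColor Area-label font attributes.
#' @slot labelSize Area-label height as a fraction of canvas height.
#' @slot captionText Optional caption text per set (default: the set labels).
#' @slot captionFontFamily,captionFontFace,captionColor,captionSize Caption font.
#' @slot captionMode "default" (outside each shape, away from the diagram
#'   center), "text" (attached to the set's exclusive-region area label) or
#'   "explicit" (user positions in `captionPositions`).
#' @slot captionPositions Numeric matrix (n x 2) used when mode is "explicit".
#' @slot captionJust Justification string for captions.
#' @slot captionDistance Gap between shape boundary and caption, canvas units.
#' @slot mainTitle,subTitle Title strings ("" = none).
#' @slot titleFontFamily,titleFontFace,titleColor,titleSize Title font.
#' @slot titlePosition,subtitlePosition Numeric (x, y) title anchors.
#' @slot margin Canvas margin fraction per side.
#' @slot rotation Diagram rotation, degrees counter-clockwise.
#' @slot invert Reflect the diagram across the vertical center axis.
#' @slot eulerEnabled Recognize Euler cases (FALSE forces plain Venn).
#' @slot scaled Request area-proportional layout.
#' @slot smallRegionThreshold Lens width (canvas units) below which a two-set
#'   intersection label is moved outside and connected by a leader line.
#' @slot tangencyGap Visible gap used at degenerate tangencies, canvas units.
#' @slot minRadius Minimum drawn radius for empty sets in Venn mode.
#' @slot samples Monte-Carlo sample count for label anchor placement.
#' @slot oracleSeed Seed of the Monte-Carlo region oracle.
#' @exportClass DiagramStyle
setClass("DiagramStyle",
  representation(
    fill = "character", alpha = "numeric",
    lineStyle = "character", lineWidth = "numeric", lineColor = "character",
    labelFontFamily = "character", labelFontFace = "character",
    labelSize = "numeric", labelColor = "character",
    captionText = "character",
    captionFontFamily = "character", captionFontFace = "character",
    captionSize = "numeric", captionColor = "character",
    captionMode = "character", captionPositions = "matrix",
    captionJust = "character", captionDistance = "numeric",
    mainTitle = "character", subTitle = "character",
    titleFontFamily = "character", titleFontFace = "character",
    titleSize = "numeric", titleColor = "character",
    titlePosition = "numeric", subtitlePosition = "numeric",
    margin = "numeric", rotation = "numeric", invert = "logical",
    eulerEnabled = "logical", scaled = "logical",
    smallRegionThreshold = "numeric", tangencyGap = "numeric",
    minRadius = "numeric", samples = "numeric", oracleSeed = "numeric"))

## Figure handle -------------------------------------------------------------

#' VennFigure: an in-memory figure handle
#'
#' Returned by [renderDiagram()] when no output path is given; wraps the
#' assembled grid graphics tree so the figure can be drawn into any open
#' device or saved later with [saveFigure()].
#'
#' @slot grob A grid `gTree` with the complete figure.
#' @slot layout The [VennLayout-class] the figure was built from.
#' @slot style The [DiagramStyle-class] used to build it.
#' @exportClass VennFigure
setClass("VennFigure",
  representation(grob = "ANY", layout = "VennLayout", style = "ANY"))
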