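#' @include AllClasses.R
NULL

#' Accessors for VennForge objects
#'
#' @param x A VennForge object.
#' @name accessors
NULL

#' @describeIn accessors Set labels of a collection, cardinality table or layout.
#' @export
setGeneric("setLabels", function(x) standardGeneric("setLabels"))

#' @describeIn accessors Number of sets.
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @describeIn accessors Named region-count vector (canonical key order).
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

#' @describeIn accessors Member identifiers, as a named list.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @describeIn accessors Shapes of a layout (list of Circle/Ellipse).
#' @export
setGeneric("shapes", function(x) standardGeneric("shapes"))

#' @describeIn accessors Diagram class string of a layout.
#' @export
setGeneric("diagramClass", function(x) standardGeneric("diagramClass"))

#' Save an in-memory figure to a file
#'
#' @param x A [VennFigure-class] handle.
#' @param path Output file path.
#' @param ... Passed on to [renderDiagram()]'s device arguments
#'   (`format`, `widthPx`, `heightPx`, `dpi`, `compression`).
#' @return The output path, invisibly.
#' @export
setGeneric("saveFigure", function(x, path, ...) standardGeneric("saveFigure"))

setMethod("setLabels", "SetCollection", function(x) x@setLabels)
setMethod("setLabels", "RegionCardinalities", function(x) x@setLabels)
setMethod("setLabels", "VennLayout", function(x) x@setLabels)
setMethod("nSets", "SetCollection", function(x) length(x@setLabels))
setMethod("nSets", "RegionCardinalities", function(x) x@nSets)
setMethod("nSets", "VennLayout", function(x) length(x@shapes))
setMethod("regionCounts", "RegionCardinalities", function(x) x@counts)
setMethod("members", "SetCollection", function(x)
  stats::setNames(x@members, x@setLabels))
setMethod("shapes", "VennLayout", function(x) x@shapes)
setMethod("diagramClass", "VennLayout", function(x) x@diagramClass)

setMethod("show", "SetCollection", function(object) {
  cat(sprintf("SetCollection with %d set(s)\n", nSets(object)))
  for (i in seq_along(object@setLabels))
    cat(sprintf("  %s: %d element(s)\n", object@setLabels[i],
                length(object@members[[i]])))
  invisible(NULL)
})

setMethod("show", "RegionCardinalities", function(object) {
  cat(sprintf("RegionCardinalities for %d set(s) [%s]\n", object@nSets,
              paste(object@setLabels, collapse = ", ")))
  lab <- vapply(names(object@counts), function(k)
    paste(object@setLabels[.keyIndices(k)], collapse = "&"), character(1))
  cat(paste(sprintf("  %-12s %g", lab, object@counts), collapse = "\n"), "\n")
  invisible(NULL)
})

setMethod("show", "Circle", function(object) {
  cat(sprintf("Circle(center = (%.4f, %.4f), radius = %.4f)\n",
              object@center[1], object@center[2], object@radius))
  invisible(NULL)
})

setMethod("show", "Ellipse", function(object) {
  cat(sprintf("Ellipse(center = (%.4f, %.4f), axes = (%.4f, %.4f), angle = %.1f)\n",
              object@center[1], object@center[2], object@semiMajor,
              object@semiMinor, object@angle))
  invisible(NULL)
})

setMethod("show", "VennLayout", function(object) {
  cat(sprintf("VennLayout [%s] with %d shape(s), %d region anchor(s), %d leader line(s)\n",
              object@diagramClass, length(object@shapes),
              length(object@regionAnchors), length(object@leaderLines)))
  invisible(NULL)
})

setMethod("show", "VennFigure", function(object) {
  cat(sprintf("VennFigure handle [%s]; draw with grid::grid.draw(figureGrob(.)) or saveFigure(., path)\n",
              object@layout@diagramClass))
  invisible(NULL)
})

#' Extract the grid grob from a figure handle
#' @param x A [VennFigure-class].
#' @return The underlying `gTree`.
#' @export
figureGrob <- function(x) {
  stopifnot(is(x, "VennFigure"))
  x@grob
}
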