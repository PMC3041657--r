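#' @include render.R
NULL

#' Build the complete labeled layout for a region table
#'
#' Runs the full layout pipeline: classify the zero pattern, check the
#' scaling request, position the shapes for the chosen case, apply rotation
#' and inversion, and attach area labels, captions and leader lines.
#'
#' @param card A validated [RegionCardinalities-class].
#' @param style A [DiagramStyle-class]; `eulerEnabled`, `scaled`, `rotation`,
#'   `invert`, margins and label settings are taken from it.
#' @return A labeled [VennLayout-class].
#' @examples
#' card <- validateCardinalities(c("1" = 70, "2" = 40, "12" = 30))
#' layout <- buildLayout(card, DiagramStyle(samples = 2e4))
#' diagramClass(layout)
#' @export
buildLayout <- function(card, style = DiagramStyle()) {
  card <- validateCardinalities(card)
  cls <- classifyDiagram(card, style@eulerEnabled)
  checkVennScaling(card, style@scaled, cls)
  layout <- if (startsWith(cls, "EULER_")) {
    layoutEuler(card, cls, scaled = style@scaled,
                tangencyGap = style@tangencyGap, minRadius = style@minRadius,
                margin = style@margin)
  } else if (cls == "VENN_2" && style@scaled) {
    layoutScaledTwoSet(card, tangencyGap = style@tangencyGap,
                       minRadius = style@minRadius, margin = style@margin)
  } else {
    layoutVenn(card, fallback = cls == "FALLBACK_VENN_3")
  }
  layout <- transformLayout(layout, style@rotation, style@invert)
  attachLabels(layout, card, style)
}

#' One-call diagram generation
#'
#' Convenience front end covering the whole pipeline: accepts raw sets (a
#' named list or [SetCollection-class]) or a region-count table (named vector
#' or [RegionCardinalities-class]), builds the labeled layout and renders it.
#'
#' @param x Input sets or region counts.
#' @param style A [DiagramStyle-class], or anything [parseStyle()] accepts.
#' @param file Output path, or `NULL` (default) to return a
#'   [VennFigure-class] handle.
#' @param ... Passed to [renderDiagram()] (`format`, `widthPx`, `heightPx`,
#'   `dpi`, `compression`).
#' @return See [renderDiagram()].
#' @examples
#' fig <- drawDiagram(list(A = letters[1:8], B = letters[5:12]),
#'                    style = DiagramStyle(samples = 2e4))
#' @export
drawDiagram <- function(x, style = DiagramStyle(), file = NULL, ...) {
  style <- parseStyle(style)
  card <- if (is(x, "RegionCardinalities")) validateCardinalities(x)
  else if (is(x, "SetCollection")) validateCardinalities(computeRegionCardinalities(x))
  else if (is.list(x) && !is.null(names(x)))
    validateCardinalities(computeRegionCardinalities(SetCollection(x)))
  else validateCardinalities(x)
  layout <- buildLayout(card, style)
  renderDiagram(layout, style, file = file, ...)
}
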