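#' @include style.R labels.R
NULL

## ---------------------------------------------------------------------------
## Figure assembly with grid.  The figure tree is device-agnostic; font sizes
## given as canvas fractions are converted to points against a 10-inch
## reference canvas (the default 3000 px at 300 dpi), so labels keep their
## proportion at the default export size and scale with point size elsewhere.

.REF_CANVAS_IN <- 10
.fontPts <- function(frac) frac * .REF_CANVAS_IN * 72

.shapeCoords <- function(shape, n = 240L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  if (is(shape, "Circle")) {
    list(x = shape@center[1] + shape@radius * cos(t),
         y = shape@center[2] + shape@radius * sin(t))
  } else {
    th <- shape@angle * pi / 180
    u <- shape@semiMajor * cos(t)
    v <- shape@semiMinor * sin(t)
    list(x = shape@center[1] + u * cos(th) - v * sin(th),
         y = shape@center[2] + u * sin(th) + v * cos(th))
  }
}

.rep4 <- function(x, n) rep_len(x, n)

.buildGrob <- function(layout, style) {
  n <- length(layout@shapes)
  fills <- grDevices::adjustcolor(.rep4(style@fill, n),
                                  alpha.f = 1) # alpha applied separately below
  alph <- .rep4(style@alpha, n)
  lty <- .rep4(style@lineStyle, n)
  lwd <- .rep4(style@lineWidth, n)
  lcol <- .rep4(style@lineColor, n)
  grobs <- list()
  ## 1. fills
  for (i in seq_len(n)) {
    co <- .shapeCoords(layout@shapes[[i]])
    grobs[[length(grobs) + 1L]] <- grid::polygonGrob(
      co$x, co$y, default.units = "npc",
      gp = grid::gpar(fill = grDevices::adjustcolor(fills[i], alpha.f = alph[i]),
                      col = NA))
  }
  ## 2. shape lines
  for (i in seq_len(n)) {
    if (lty[i] == "blank") next
    co <- .shapeCoords(layout@shapes[[i]])
    grobs[[length(grobs) + 1L]] <- grid::polygonGrob(
      co$x, co$y, default.units = "npc",
      gp = grid::gpar(fill = NA, col = lcol[i], lwd = lwd[i], lty = lty[i]))
  }
  ## 3. area labels (a region with a leader line prints at the line's end)
  leaderRegion <- vapply(layout@leaderLines, `[[`, character(1), "region")
  for (key in names(layout@regionLabels)) {
    li <- match(key, leaderRegion)
    pos <- if (!is.na(li)) layout@leaderLines[[li]]$to else layout@regionAnchors[[key]]
    grobs[[length(grobs) + 1L]] <- grid::textGrob(
      layout@regionLabels[[key]], pos[1], pos[2], default.units = "npc",
      gp = grid::gpar(fontfamily = style@labelFontFamily,
                      fontface = style@labelFontFace,
                      fontsize = .fontPts(style@labelSize),
                      col = style@labelColor))
  }
  ## 4. leader lines
  for (l in layout@leaderLines) {
    grobs[[length(grobs) + 1L]] <- grid::segmentsGrob(
      l$from[1], l$from[2], l$to[1], l$to[2] - 0.6 * style@labelSize,
      default.units = "npc",
      gp = grid::gpar(col = style@labelColor, lwd = 1))
  }
  ## 5. captions
  for (cap in layout@captionAnchors) {
    just <- if (cap$just == "center") "centre" else cap$just
    grobs[[length(grobs) + 1L]] <- grid::textGrob(
      cap$text, cap$pos[1], cap$pos[2], just = just, default.units = "npc",
      gp = grid::gpar(fontfamily = style@captionFontFamily,
                      fontface = style@captionFontFace,
                      fontsize = .fontPts(style@captionSize),
                      col = style@captionColor))
  }
  ## 6. titles
  if (nzchar(style@mainTitle))
    grobs[[length(grobs) + 1L]] <- grid::textGrob(
      style@mainTitle, style@titlePosition[1], style@titlePosition[2],
      default.units = "npc",
      gp = grid::gpar(fontfamily = style@titleFontFamily,
                      fontface = style@titleFontFace,
                      fontsize = .fontPts(style@titleSize),
                      col = style@titleColor))
  if (nzchar(style@subTitle))
    grobs[[length(grobs) + 1L]] <- grid::textGrob(
      style@subTitle, style@subtitlePosition[1], style@subtitlePosition[2],
      default.units = "npc",
      gp = grid::gpar(fontfamily = style@titleFontFamily, fontface = "plain",
                      fontsize = .fontPts(style@titleSize * 0.75),
                      col = style@titleColor))
  grid::gTree(children = do.call(grid::gList, grobs),
              vp = grid::viewport(width = grid::unit(1, "snpc"),
                                  height = grid::unit(1, "snpc")))
}

.formats <- c(tiff = "tiff", tif = "tiff", png = "png", jpeg = "jpeg",
              jpg = "jpeg", bmp = "bmp", svg = "svg")

#' Render a labeled layout to a file or an in-memory figure handle
#'
#' Applies the style to the layout and either writes a figure file (format
#' inferred from the extension unless given: TIFF — the default export
#' format — PNG, JPEG, BMP or SVG, at the requested pixel dimensions and
#' resolution) or, when `file` is `NULL`, returns a [VennFigure-class] handle
#' whose grid tree can be drawn into any open device or saved later.
#' Drawing order: shape fills, shape lines, area labels, leader lines,
#' captions, titles.
#'
#' @param layout A labeled [VennLayout-class] (see [attachLabels()]).
#' @param style A [DiagramStyle-class].
#' @param file Output path, or `NULL` for an in-memory handle.
#' @param format Output format; default inferred from the file extension.
#' @param widthPx,heightPx Raster dimensions in pixels (default 3000 x 3000).
#' @param dpi Resolution written to the file metadata (default 300).
#' @param compression TIFF compression (default "lzw").
#' @return The output path (invisibly) when `file` is given, otherwise a
#'   [VennFigure-class].
#' @export
renderDiagram <- function(layout, style = DiagramStyle(), file = NULL,
                          format = NULL, widthPx = 3000, heightPx = 3000,
                          dpi = 300, compression = "lzw") {
  stopifnot(is(layout, "VennLayout"), is(style, "DiagramStyle"))
  if (widthPx <= 0 || heightPx <= 0 || dpi <= 0)
    .vfError("invalidInputError", "dimensions and dpi must be positive")
  grob <- .buildGrob(layout, style)
  if (is.null(file))
    return(new("VennFigure", grob = grob, layout = layout, style = style))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(file))
    if (!nzchar(ext) || is.na(.formats[ext]))
      .vfError("formatError", sprintf(
        "cannot infer format from \"%s\" (supported: %s)", file,
        paste(unique(.formats), collapse = ", ")))
    format <- .formats[[ext]]
  } else {
    format <- tolower(format)
    if (!format %in% .formats)
      .vfError("formatError", sprintf("unsupported format \"%s\"", format))
    format <- .formats[[format]]
  }
  dir <- dirname(file)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    .vfError("ioError", sprintf("output directory \"%s\" is not writable", dir))
  wIn <- widthPx / dpi
  hIn <- heightPx / dpi
  opened <- switch(format,
    tiff = grDevices::tiff(file, width = widthPx, height = heightPx,
                           units = "px", res = dpi, compression = compression,
                           type = "cairo"),
    png = grDevices::png(file, width = widthPx, height = heightPx,
                         units = "px", res = dpi, type = "cairo"),
    jpeg = grDevices::jpeg(file, width = widthPx, height = heightPx,
                           units = "px", res = dpi, quality = 95,
                           type = "cairo"),
    bmp = grDevices::bmp(file, width = widthPx, height = heightPx,
                         units = "px", res = dpi, type = "cairo"),
    svg = grDevices::svg(file, width = wIn, height = hIn))
  ok <- FALSE
  on.exit({
    grDevices::dev.off()
    if (!ok && file.exists(file)) unlink(file)
  })
  grid::grid.newpage()
  grid::grid.rect(gp = grid::gpar(fill = "white", col = NA))
  grid::grid.draw(grob)
  ok <- TRUE
  invisible(file)
}

#' @rdname saveFigure
setMethod("saveFigure", "VennFigure", function(x, path, ...) {
  args <- list(...)
  style <- args$style
  if (is.null(style)) style <- x@style
  if (is.null(style)) style <- DiagramStyle()
  do.call(renderDiagram, c(list(layout = x@layout, style = style, file = path),
                           args[setdiff(names(args), "style")]))
})
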