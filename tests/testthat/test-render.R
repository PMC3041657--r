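test_that("raster outputs match the requested dimensions and resolution", {
  skip_if_not_installed("png")
  skip_if_not_installed("tiff")
  d <- withr::local_tempdir()
  card <- validateCardinalities(c("1" = 5, "2" = 4, "12" = 2))
  layout <- buildLayout(card, fastStyle())

  p <- file.path(d, "fig.png")
  renderDiagram(layout, fastStyle(), file = p, widthPx = 600, heightPx = 450,
                dpi = 150)
  img <- png::readPNG(p, info = TRUE)
  info <- attr(img, "info")
  expect_identical(info$dim, c(600L, 450L))
  expect_equal(info$dpi[1], 150, tolerance = 0.01)

  t <- file.path(d, "fig.tiff")
  renderDiagram(layout, fastStyle(), file = t, widthPx = 400, heightPx = 400,
                dpi = 200)
  timg <- tiff::readTIFF(t, info = TRUE)
  tinfo <- attributes(timg)
  expect_identical(tinfo$width, 400L)
  expect_identical(tinfo$length, 400L)
  expect_equal(tinfo$x.resolution, 200)
  expect_identical(tinfo$compression, "LZW")

  for (ext in c("jpg", "bmp", "svg")) {
    f <- file.path(d, paste0("fig.", ext))
    renderDiagram(layout, fastStyle(), file = f, widthPx = 300, heightPx = 300)
    expect_true(file.exists(f))
  }
})

test_that("without a path a figure handle is returned and nothing is written", {
  d <- withr::local_tempdir()
  before <- list.files(d)
  card <- validateCardinalities(c("1" = 5))
  fig <- renderDiagram(buildLayout(card, fastStyle()), fastStyle())
  expect_s4_class(fig, "VennFigure")
  expect_true(grid::is.grob(figureGrob(fig)))
  expect_identical(list.files(d), before)

  out <- file.path(d, "later.png")
  saveFigure(fig, out, widthPx = 300, heightPx = 300, dpi = 100)
  expect_true(file.exists(out))
})

test_that("every region count appears exactly once as rendered label text", {
  counts <- c("1" = 12, "2" = 0, "3" = 7, "12" = 3, "13" = 0, "23" = 5,
              "123" = 2)
  card <- validateCardinalities(counts, nSets = 3)
  fig <- renderDiagram(buildLayout(card, fastStyle(euler = FALSE)), fastStyle())
  texts <- grobTexts(figureGrob(fig))
  numerals <- texts[grepl("^[0-9]+$", texts)]
  expect_identical(sort(as.numeric(numerals)), sort(unname(counts)))
})

test_that("rendering is deterministic: same inputs give identical SVG bytes", {
  d <- withr::local_tempdir()
  card <- validateCardinalities(c("1" = 40, "2" = 25, "12" = 10))
  style <- fastStyle(scaled = TRUE, main_title = "stable")
  f1 <- file.path(d, "a.svg"); f2 <- file.path(d, "b.svg")
  renderDiagram(buildLayout(card, style), style, file = f1)
  renderDiagram(buildLayout(card, style), style, file = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("bad paths and formats raise classed errors without side effects", {
  card <- validateCardinalities(c("1" = 5))
  layout <- buildLayout(card, fastStyle())
  expect_error(renderDiagram(layout, fastStyle(),
                             file = "/no/such/dir/fig.png"),
               class = "ioError")
  expect_error(renderDiagram(layout, fastStyle(), file = "fig.xyz"),
               class = "formatError")
  expect_error(renderDiagram(layout, fastStyle(), file = tempfile(),
                             format = "gif"),
               class = "formatError")
})
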