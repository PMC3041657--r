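Package: VennForge
Title: Area-Proportional Venn and Euler Diagrams for Set Overlap Visualization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes all 2^n - 1 region cardinalities for one to four named
    element sets (or accepts region counts directly), classifies the overlap
    pattern into a Venn or Euler diagram case, solves the circle geometry in
    closed form where the layout is determined (including area-proportional
    two-set diagrams via monotone inversion of the circle-circle lens area),
    and renders publication-quality figures to TIFF, PNG, JPEG, BMP or SVG
    with an extensively customizable style model. A seeded Monte-Carlo region
    oracle provides region areas and label anchor points for arbitrary
    circle/ellipse arrangements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, grid, grDevices, stats, utils, tools, jsonlite, optparse
Suggests: testthat (>= 3.0.0), withr, png, tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'VennForge-package.R'
    'setAlgebra.R'
    'classify.R'
    'geometry.R'
    'transforms.R'
    'layouts.R'
    'labels.R'
    'style.R'
    'render.R'
    'pipeline.R'
    'cli.R'
    'errors.R'
    'readers.R'
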