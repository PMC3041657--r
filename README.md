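# VennForge

Venn and Euler diagrams for set-overlap visualization, built for
bioinformatics pipelines: gene lists, variant calls, peak sets — any
collections of identifiers whose overlaps need a clear, publication-quality
figure.

Given 1–4 named sets (or a region-count table supplied directly), VennForge

* computes all 2^n − 1 **region cardinalities** — for every non-empty subset
  S of the sets, the number of elements belonging to exactly the sets in S;
* **classifies** the zero/non-zero pattern into a Venn or Euler case
  (inclusions, disjoint sets, nested chains, …), falling back to a standard
  Venn diagram with explicit zeros for patterns that circles and ellipses
  cannot realize;
* solves the **geometry**: two-set diagrams are exactly area-proportional,
  using the circle–circle lens area
  A∩(d) = r₁² acos((d²+r₁²−r₂²)/(2dr₁)) + r₂² acos((d²+r₂²−r₁²)/(2dr₂)) −
  ½√((−d+r₁+r₂)(d+r₁−r₂)(d−r₁+r₂)(d+r₁+r₂)),
  which is strictly decreasing in the center distance d and therefore
  invertible by bisection (`solveDistance()`).  For three circles the
  pairwise distances fix a unique triangle of centers with no freedom left
  for the triple overlap, so scaled three-set Venn requests are refused
  rather than drawn wrong;
* **renders** TIFF (default, LZW at 300 dpi), PNG, JPEG, BMP or SVG with a
  fully parameterized style model, or returns an in-memory figure handle
  when no filename is given.

A seeded Monte-Carlo region oracle (`regionAreasAndCentroids()`) provides
region areas and label anchors for arbitrary circle/ellipse arrangements and
doubles as the independent measuring instrument in the test suite.

## Worked example

Two response signatures shipped with the package (one identifier per line):

```r
library(VennForge)
up <- readLines(system.file("extdata", "tumor_up.txt", package = "VennForge"))
dn <- readLines(system.file("extdata", "tumor_down.txt", package = "VennForge"))
sets <- SetCollection(list(up = up, down = dn))
card <- computeRegionCardinalities(sets)
card
#> RegionCardinalities for 2 set(s) [up, down]
#>   up           6
#>   down         4
#>   up&down      2
classifyDiagram(card)
#> [1] "VENN_2"
```

Six genes are exclusive to `up`, four to `down`, and two are shared — so all
three regions are occupied and the case is a standard two-set Venn diagram.
An area-proportional figure:

```r
lay <- buildLayout(card, DiagramStyle(scaled = TRUE))
lay
#> VennLayout [VENN_2] with 2 shape(s), 3 region anchor(s), 0 leader line(s)
drawDiagram(card, DiagramStyle(scaled = TRUE), file = "overlap.tiff")
```

In the scaled layout the two circle areas are proportional to 8 and 6 (the
set totals) and the lens to 2, solved to 10⁻⁹ in area.  The closed form is
easy to sanity-check at the symmetric point: two unit circles at distance 1
overlap in 2π/3 − √3/2 ≈ 1.2284, and

```r
solveDistance(1, 1, 2*pi/3 - sqrt(3)/2)
#> [1] 1
```

With no filename, the renderer returns a handle you can draw or save later:

```r
fig <- drawDiagram(card, DiagramStyle(scaled = TRUE))
fig
#> VennFigure handle [VENN_2]; draw with grid::grid.draw(figureGrob(.)) or saveFigure(., path)
```

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","vennforge.R",package="VennForge"))')" \
    inst/extdata/tumor_up.txt inst/extdata/tumor_down.txt \
    --scaled --out overlap.tiff
```

Inputs: list files (one element per line, file stem = set name),
`--sets-table` (two-column set/element table), `--sets-json`
(name → array mapping), or `--counts` (direct region counts).  Style comes
from `--config style.json` (see `?parseStyle` for the schema) plus the
`--scaled`, `--no-euler`, `--rotate`, `--invert` switches.  Each failure
mode has its own exit code (e.g. 3 for more than four sets, 5 for an
unsupported scaling request).

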