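---
title: "Geometry and classification of Venn and Euler diagrams in VennForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and classification of Venn and Euler diagrams in VennForge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VennForge)
```

## The problem

Comparing gene lists, variant calls, peak sets or any other collections of
identifiers is a routine task, and the standard display is a Venn diagram:
for $n$ sets, all $2^n - 1$ regions formed by their interactions, each
printed with the number of elements that belong to exactly that combination
of sets.  When some regions are empty, an Euler diagram — which draws only
the occupied regions, using nesting and separation — is often clearer and
more accurate.  VennForge computes the region table from raw sets (or accepts
it directly), decides which diagram case applies, solves the circle geometry,
and renders a publication-quality figure.

The engine supports Venn diagrams of one to four sets and Euler recognition
for two and three sets.  Larger inputs are refused: five-set diagrams lose
the instant readability that motivates the display in the first place, and
the layout families below do not extend to them.

## Region model

A region is keyed by the subset of sets it belongs to, written as sorted
1-based indices (`"1"`, `"13"`, `"123"`).  `computeRegionCardinalities()`
tallies each element's membership bit-vector, so the counts are *exclusive*:
the sum over all regions equals the size of the union, and a set's total is
the sum over regions containing its index.  Duplicate identifiers within one
set are collapsed — the inputs are sets, and list-style inputs with repeats
would otherwise inflate counts silently.  Direct count input
(`validateCardinalities()`) fills absent regions with zero rather than
rejecting them, since sparse tables are the natural way to write Euler-ish
patterns down.

## Two circles: the lens area and its inversion

A set drawn as a circle of radius $r$ has area $A = \pi r^2$.  For two
circles with radii $r_1, r_2$ at center distance $d$, the intersection (the
*lens*) has the closed form

$$A_\cap(d) = r_1^2 \cos^{-1}\!\frac{d^2+r_1^2-r_2^2}{2dr_1}
            + r_2^2 \cos^{-1}\!\frac{d^2+r_2^2-r_1^2}{2dr_2}
            - \tfrac12\sqrt{(-d+r_1+r_2)(d+r_1-r_2)(d-r_1+r_2)(d+r_1+r_2)}$$

on $|r_1-r_2| < d < r_1+r_2$, with the obvious plateaus outside (full
inclusion, disjoint).  $A_\cap$ is strictly decreasing in $d$ on that
interval, so a target intersection area determines the distance uniquely.
`solveDistance()` inverts it by bisection: monotonicity guarantees
convergence, the bracket $[|r_1-r_2|,\ r_1+r_2]$ is exact, and we stop when
the achieved area is within `tol` (default $10^{-9}$ in area units, at most
200 iterations; the interval halves 60-odd times before hitting double
precision, so the cap is never the binding constraint).  Bisection was chosen
over Newton-type updates because the derivative degenerates at both bracket
ends and robustness matters more here than iteration count.

This is exactly why **two-set diagrams are exactly scalable**: radii come
from the set totals, the distance from the intersection count, and every
region area is then proportional to its count by construction
(`layoutScaledTwoSet()`).

## Three circles: why scaling is refused

Given three radii and the three pairwise intersection areas, the three
center distances follow from the two-circle inversion — and three distances
determine a unique triangle.  The construction never consults the triple
intersection: the drawn triple region is whatever the triangle produces,
even if the true triple count is zero.  Circles simply have one degree of
freedom too few.  `placeThreeCircles()` implements the triangle construction
(A at the origin, B on the positive x axis, C in the upper half-plane;
rotation and inversion produce the other orientations) and raises an
`unrealizableArrangementError` when the solved distances violate the
triangle inequality.  Because the triple region cannot be honored,
area-proportional *Venn* layouts are refused for three sets — and for four,
where the same degrees-of-freedom argument applies even more strongly — with
an `unsupportedScalingError` rather than a silently wrong picture.

## The Monte-Carlo region oracle

Ellipse-region areas have no convenient closed form, and label anchors are
needed for every drawn region, so one sampling oracle
(`regionAreasAndCentroids()`) is the single source of truth for both:
uniform samples over the joint bounding box, each assigned to the region
keyed by the shapes containing it; areas are box-area times hit fractions,
centroids are hit means.  It is seeded (default seed 20110126) and restores
the caller's RNG state, so identical inputs give identical figures.  The
standard error of an estimated area $A$ from $N$ samples in a box of area
$B$ is $B\sqrt{p(1-p)/N}$ with $p = A/B$; tests compare closed forms against
the oracle at $3$ standard errors.  Defaults: $10^6$ samples where the
oracle is the measurement instrument, $10^5$ for routine label placement.

Monte-Carlo centroids can fall outside non-convex regions (the centroid of a
crescent, or of an annulus, is not in it).  When that happens the anchor
falls back to the in-region grid point (201×201 over the bounding box)
nearest the centroid — deterministic and always inside, at the cost of
hugging the region's waist in extreme shapes.

## Diagram classification

`classifyDiagram()` maps the zero/non-zero pattern of the counts to a case.
With Euler recognition off, with four sets, or with no empty region, the
result is plain `VENN_n`.  Both two-set Euler cases (inclusion, disjoint)
are recognized; a two-set pattern with an entirely empty set has no
two-circle Euler drawing and is rendered as a Venn diagram with its zero.

For three sets, the implemented families are matched in a fixed priority
order over all six role permutations $(i, j, k)$:

| family | relation | scalable |
|---|---|---|
| `EULER_3_DISJOINT` | three pairwise disjoint sets | yes |
| `EULER_3_CHAIN` | $i \subseteq j \subseteq k$ | yes |
| `EULER_3_NESTED_DISJOINT` | $i \subseteq j$, $k$ disjoint | yes |
| `EULER_3_TWO_IN_ONE_DISJOINT` | $i, j \subseteq k$, $i \cap j = \emptyset$ | no |
| `EULER_3_TWO_IN_ONE_OVERLAP` | $i, j \subseteq k$, $i,j$ overlap | no |
| `EULER_3_PAIR_DISJOINT` | $i,j$ overlap, $k$ disjoint | no |
| `EULER_3_NESTED_IN_OVERLAP` | $i \subseteq j\setminus k$, $j,k$ overlap | no |
| `EULER_3_IN_INTERSECTION` | $i \subseteq j \cap k$ | no |
| `EULER_3_NO_EXCLUSIVE` | $i$ has no exclusive elements, all else occupied | no |

Every other pattern — including any pattern with an empty set, and patterns
with no circle/ellipse realization at all, such as two disjoint sets that
exactly comprise the third — returns `FALLBACK_VENN_3` and is drawn as a
standard Venn diagram with explicit zeros.  The fallback is deliberately
broad: it is always drawable, and a correct-if-plain Venn beats a wrong
Euler.  The exact catalogue of realizable three-set cases is larger than
what any circle-template family covers (some would need polygons or
iterative fitting, which this engine intentionally does not do), so the
table above should be read as the supported subset, not a complete taxonomy.

The *scalable* subset is exactly the families whose geometry is fully
determined by set totals plus inclusion/disjointness — no partial two-way
overlap anywhere.  There, radii are $\sqrt{A/\pi}$ of the totals and nesting
offsets/gaps derive from the distance solver.  A scaled request for any
other Euler family falls back to template proportions with a warning rather
than an error, since the template still draws the *topology* faithfully.

Template constants (nesting ratios, gaps) are display conventions; tests
assert them only through the oracle: occupied regions get positive area,
empty regions get area below $10^{-3}$ of the canvas.  When a "free" region
of a family is also zero (equal sets in a chain, say) the template collapses
the corresponding slack to concentric equal circles so the zero stays exact.

## Canvas, units, and numeric conventions

Layouts are computed in convenient abstract units and then uniformly
rescaled and centered into the unit square, y increasing upward, with a
configurable margin (default 0.05 per side).  Everything the user configures
in length units — caption distance, tangency gap (default 0.01), minimum
radius for empty sets in Venn mode (0.02), the small-region threshold for
leader lines (0.04) — is expressed in canvas units; gaps applied before the
rescale are converted through a first no-gap fitting pass so they come out
at the requested canvas size.  Degenerate scaled two-set cases use tangency
plus the visible gap (external for disjoint, internal for inclusion; exactly
equal totals give concentric circles).  In a scaled two-set diagram whose
lens is narrower than the threshold, the numeric label moves above the
shapes and a leader line connects it to the lens; the anchor stored in the
layout stays inside the region, the printed text sits at the line's end.

Rotation (any angle, counter-clockwise about the canvas center) and
inversion (reflection across the vertical center axis, applied before the
rotation) are rigid maps applied to shapes, anchors and leader lines alike,
so region areas and label values are invariant.

## Style model and rendering

The style surface covers the four graphical groups — shape fill (color +
alpha per shape), shape line (type/width/color per shape, including
`"blank"`), labels (font family/face/size/color for area labels and
captions, three caption placement modes), and titles — plus the layout
switches (`euler`, `scaled`, `rotation`, `invert`, `margin`).  Defaults aim
at a sensible figure with no configuration: distinct semi-transparent fills
(alpha 0.5), solid black outlines of width 2, sans-serif labels at 2.5% of
the canvas height.  Font sizes given as canvas fractions are converted to
points against a 10-inch reference canvas (the default 3000 px at 300 dpi
export), so other export sizes scale by point size.  Unknown configuration
keys warn and are ignored; invalid values fail naming the key; color names
are validated against the R color table (or `#RRGGBB[AA]`).

Output is TIFF by default (LZW, 3000×3000 px at 300 dpi), with PNG, JPEG,
BMP and SVG available; with no filename the assembled figure tree is
returned as an in-memory handle (`VennFigure`) that can be drawn into any
open device or saved later.  Drawing order is fixed: fills, outlines, area
labels, leader lines, captions, titles.  Cairo SVG output is byte-stable,
which is what the reproducibility tests assert.

## The random-set generator

`generateRandomSets()` is the package's test fixture: each of `universeSize`
elements joins each set independently with probability `membershipProb`,
under a fixed seed.  Independent Bernoulli membership produces every
overlap pattern with known expected counts, which is what the property
suites need; it does **not** emulate the correlation structure of real gene
lists (shared pathways, nested contrasts), heavy-tailed set sizes, or
identifier noise.  Passing tests therefore demonstrate the combinatorics and
geometry are right, not that any biological overlap is typical.  Suite
problem sizes — universes up to ~200 elements, 100 seeded fixtures,
$2\times10^4$ oracle samples for routine label placement and $10^6$ where
the oracle is used as a measuring device — were chosen so the full suite
runs in well under a minute while keeping Monte-Carlo bands at the $3\sigma$
level meaningful.

## Known limitations

* Euler coverage is the family table above; unsupported but realizable
  patterns fall back to Venn rather than attempting iterative layout.
* Ellipse-based or polygon-based Euler fitting (which would make more
  three-set cases area-accurate) is out of scope by design.
* Scaled accuracy claims apply to two-set layouts and the scalable Euler
  subset; everywhere else region areas are schematic.
* Caption auto-placement optimizes for the built-in arrangements; dense
  custom rotations may need explicit caption positions.
* At most four sets, by design.
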