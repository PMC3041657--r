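#' @include setAlgebra.R
NULL

## ---------------------------------------------------------------------------
## Diagram-case classification.
##
## A Venn diagram draws all 2^n - 1 regions, zeros included; an Euler diagram
## draws only the non-zero regions, using nesting and separation.  The
## classifier maps the zero/non-zero pattern of the region counts to one
## diagram case.  All two-set patterns and the majority of three-set patterns
## have a circle realization; three-set patterns without one (for example two
## disjoint sets that exactly comprise the third) fall back to a standard
## Venn diagram.  Four-set diagrams are always drawn as Venn.

.vennClass <- function(n) paste0("VENN_", n)

#' Enumerated diagram classes
#'
#' @return Character vector of every class [classifyDiagram()] can return.
#' @export
diagramClasses <- function() c(
  "VENN_1", "VENN_2", "VENN_3", "VENN_4",
  "EULER_2_INCLUSION", "EULER_2_DISJOINT",
  "EULER_3_DISJOINT", "EULER_3_CHAIN", "EULER_3_NESTED_DISJOINT",
  "EULER_3_TWO_IN_ONE_DISJOINT", "EULER_3_TWO_IN_ONE_OVERLAP",
  "EULER_3_PAIR_DISJOINT", "EULER_3_NESTED_IN_OVERLAP",
  "EULER_3_IN_INTERSECTION", "EULER_3_NO_EXCLUSIVE",
  "FALLBACK_VENN_3")

## two-set patterns; nz is the named logical vector counts > 0.
## Returns list(class, inner) where inner is the nested set index (or NA).
.classify2 <- function(nz) {
  if (nz[["1"]] && nz[["2"]] && nz[["12"]])
    return(list(class = "VENN_2", inner = NA_integer_))
  if (nz[["12"]] && !nz[["2"]])                    # B inside A (or equal)
    return(list(class = "EULER_2_INCLUSION", inner = 2L))
  if (nz[["12"]] && !nz[["1"]])                    # A inside B
    return(list(class = "EULER_2_INCLUSION", inner = 1L))
  if (!nz[["12"]] && nz[["1"]] && nz[["2"]])
    return(list(class = "EULER_2_DISJOINT", inner = NA_integer_))
  ## one set empty: no two-circle Euler realization; draw the Venn form
  list(class = "VENN_2", inner = NA_integer_)
}

## three-set pattern families, matched over the 6 permutations (i, j, k) in a
## fixed priority order; first match wins, everything else is the fallback.
.perms3 <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))

.k <- function(...) paste(sort(c(...)), collapse = "")

## each predicate takes nz and the permutation (i, j, k)
.eulerFamilies3 <- list(
  ## three pairwise disjoint non-empty sets
  EULER_3_DISJOINT = function(z, i, j, k)
    z[.k(i)] && z[.k(j)] && z[.k(k)] &&
    !z[.k(i,j)] && !z[.k(i,k)] && !z[.k(j,k)] && !z[.k(i,j,k)],
  ## i inside j inside k (equalities allowed)
  EULER_3_CHAIN = function(z, i, j, k)
    z[.k(i,j,k)] && !z[.k(i)] && !z[.k(j)] && !z[.k(i,j)] && !z[.k(i,k)],
  ## i inside j; k disjoint from both
  EULER_3_NESTED_DISJOINT = function(z, i, j, k)
    z[.k(i,j)] && z[.k(k)] &&
    !z[.k(i)] && !z[.k(i,k)] && !z[.k(j,k)] && !z[.k(i,j,k)],
  ## i and j disjoint, both inside k, with k-only elements left over
  EULER_3_TWO_IN_ONE_DISJOINT = function(z, i, j, k)
    z[.k(i,k)] && z[.k(j,k)] && z[.k(k)] &&
    !z[.k(i)] && !z[.k(j)] && !z[.k(i,j)] && !z[.k(i,j,k)],
  ## i and j properly overlapping, both inside k
  EULER_3_TWO_IN_ONE_OVERLAP = function(z, i, j, k)
    z[.k(i,k)] && z[.k(j,k)] && z[.k(i,j,k)] && z[.k(k)] &&
    !z[.k(i)] && !z[.k(j)] && !z[.k(i,j)],
  ## i and j properly overlapping; k disjoint from both
  EULER_3_PAIR_DISJOINT = function(z, i, j, k)
    z[.k(i)] && z[.k(j)] && z[.k(i,j)] && z[.k(k)] &&
    !z[.k(i,k)] && !z[.k(j,k)] && !z[.k(i,j,k)],
  ## i inside j's exclusive part; j and k properly overlapping
  EULER_3_NESTED_IN_OVERLAP = function(z, i, j, k)
    z[.k(i,j)] && z[.k(j)] && z[.k(j,k)] && z[.k(k)] &&
    !z[.k(i)] && !z[.k(i,k)] && !z[.k(i,j,k)],
  ## i inside the intersection of j and k
  EULER_3_IN_INTERSECTION = function(z, i, j, k)
    z[.k(i,j,k)] && z[.k(j,k)] && z[.k(j)] && z[.k(k)] &&
    !z[.k(i)] && !z[.k(i,j)] && !z[.k(i,k)],
  ## i has no exclusive elements but every other region is occupied
  EULER_3_NO_EXCLUSIVE = function(z, i, j, k)
    !z[.k(i)] && z[.k(j)] && z[.k(k)] && z[.k(i,j)] && z[.k(i,k)] &&
    z[.k(j,k)] && z[.k(i,j,k)]
)

## Returns list(class, perm) for a three-set zero pattern.
.classify3 <- function(nz) {
  for (fam in names(.eulerFamilies3)) {
    pred <- .eulerFamilies3[[fam]]
    for (p in .perms3) {
      if (pred(nz, p[1], p[2], p[3]))
        return(list(class = fam, perm = p))
    }
  }
  list(class = "FALLBACK_VENN_3", perm = c(1L, 2L, 3L))
}

#' Classify a region table into a Venn or Euler diagram case
#'
#' With `eulerEnabled = FALSE`, with four sets, or when no region is empty,
#' the standard Venn case for n sets is returned.  Otherwise the zero/non-zero
#' pattern of the counts selects one of the implemented Euler cases; three-set
#' patterns with no circle/ellipse realization (and patterns outside the
#' implemented family, including any empty set) return `"FALLBACK_VENN_3"`,
#' which is drawn as a standard Venn diagram with explicit zero labels.
#'
#' @param card A validated [RegionCardinalities-class].
#' @param eulerEnabled Recognize Euler cases (default TRUE); FALSE always
#'   yields `VENN_n`.
#' @return A single string from [diagramClasses()].
#' @examples
#' card <- validateCardinalities(c("1" = 5, "12" = 2), nSets = 2)
#' classifyDiagram(card)                       # EULER_2_INCLUSION
#' classifyDiagram(card, eulerEnabled = FALSE) # VENN_2
#' @export
classifyDiagram <- function(card, eulerEnabled = TRUE) {
  stopifnot(is(card, "RegionCardinalities"))
  n <- card@nSets
  nz <- card@counts > 0
  if (!eulerEnabled || n == 1L || n == 4L || all(nz)) return(.vennClass(n))
  if (n == 2L) return(.classify2(nz)$class)
  .classify3(nz)$class
}
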