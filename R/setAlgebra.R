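#' @include AllClasses.R
NULL

#' Region cardinalities of a set collection
#'
#' Tallies, for every non-empty subset S of the input sets, the number of
#' elements that belong to exactly the sets in S.  These exclusive counts are
#' the "partial areas" a Venn diagram displays: all `2^n - 1` of them, zeros
#' included.  Set totals are recoverable as the sum of the counts over all
#' regions containing that set's index.
#'
#' @param sets A [SetCollection-class], or a named list accepted by
#'   [SetCollection()].
#' @return A [RegionCardinalities-class] object.
#' @examples
#' computeRegionCardinalities(list(A = c(1, 2, 3), B = c(3, 4)))
#' @export
computeRegionCardinalities <- function(sets) {
  if (!is(sets, "SetCollection")) sets <- SetCollection(sets)
  n <- nSets(sets)
  universe <- unique(unlist(sets@members, use.names = FALSE))
  counts <- stats::setNames(numeric(2^n - 1L), regionKeys(n))
  if (length(universe)) {
    ## membership id of each element: sum of 2^(i-1) over the sets holding it
    id <- integer(length(universe))
    for (i in seq_len(n))
      id <- id + bitwShiftL(1L, i - 1L) * (universe %in% sets@members[[i]])
    tab <- table(id)
    keys <- vapply(as.integer(names(tab)), .keyFromId, character(1), n = n)
    counts[keys] <- as.numeric(tab)
  }
  new("RegionCardinalities", nSets = n, counts = counts,
      setLabels = sets@setLabels)
}

#' Validate (and zero-fill) a user-supplied region-count table
#'
#' Accepts the partial areas of a diagram directly, mirroring count-based
#' input: keys are strings of sorted 1-based set indices ("1", "12", "123").
#' Absent regions are filled with zero; negative counts, more than four sets
#' and all-zero tables are rejected.
#'
#' @param counts Named numeric vector or list of non-negative region counts,
#'   or an existing [RegionCardinalities-class] (revalidated and returned).
#' @param nSets Number of sets; by default inferred from the largest index
#'   appearing in the keys.
#' @param setLabels Optional display labels (defaults to "A", "B", "C", "D").
#' @return A [RegionCardinalities-class] with all `2^n - 1` keys materialized.
#' @examples
#' validateCardinalities(c("1" = 5, "12" = 2), nSets = 2) # "2" filled as 0
#' @export
validateCardinalities <- function(counts, nSets = NULL, setLabels = NULL) {
  if (is(counts, "RegionCardinalities")) {
    methods::validObject(counts)
    if (sum(counts@counts) == 0)
      .vfError("emptyDiagramError", "all region counts are zero")
    return(counts)
  }
  counts <- unlist(counts)
  if (length(counts) == 0L || is.null(names(counts)) || any(!nzchar(names(counts))))
    .vfError("invalidInputError", "counts must be named by region keys such as \"1\", \"12\"")
  if (!is.numeric(counts) || anyNA(counts))
    .vfError("invalidInputError", "region counts must be numeric and non-missing")
  if (any(counts < 0))
    .vfError("invalidInputError", "region counts must be non-negative")
  if (any(counts != round(counts)))
    .vfError("invalidInputError", "region counts must be whole numbers")
  idx <- lapply(names(counts), function(k) {
    i <- .keyIndices(k)
    if (length(i) == 0L || anyNA(i) || any(i < 1L) || is.unsorted(i, strictly = TRUE))
      .vfError("invalidInputError", sprintf(
        "malformed region key \"%s\" (use sorted set indices, e.g. \"13\")", k))
    i
  })
  maxIdx <- max(unlist(idx))
  if (is.null(nSets)) nSets <- maxIdx
  if (length(nSets) != 1L || nSets != as.integer(nSets) || nSets < 1L || nSets > 4L)
    .vfError("unsupportedSizeError", sprintf(
      "diagrams support 1 to 4 sets, got %s", format(nSets)))
  nSets <- as.integer(nSets)
  if (maxIdx > nSets)
    .vfError("invalidInputError", sprintf(
      "region key references set %d but nSets = %d", maxIdx, nSets))
  if (anyDuplicated(names(counts)))
    .vfError("invalidInputError", "duplicated region keys in counts")
  full <- stats::setNames(numeric(2^nSets - 1L), regionKeys(nSets))
  full[names(counts)] <- as.numeric(counts)
  if (sum(full) == 0)
    .vfError("emptyDiagramError", "all region counts are zero")
  if (is.null(setLabels)) setLabels <- c("A", "B", "C", "D")[seq_len(nSets)]
  new("RegionCardinalities", nSets = nSets, counts = full, setLabels = setLabels)
}

#' Per-set totals from a region table
#'
#' @param card A [RegionCardinalities-class].
#' @return Named numeric vector: for each set, the sum of all region counts
#'   whose key contains that set's index (i.e. the set's cardinality).
#' @export
setTotals <- function(card) {
  stopifnot(is(card, "RegionCardinalities"))
  n <- card@nSets
  tot <- vapply(seq_len(n), function(i) {
    has <- vapply(names(card@counts), function(k) i %in% .keyIndices(k),
                  logical(1))
    sum(card@counts[has])
  }, numeric(1))
  stats::setNames(tot, card@setLabels)
}

## pairwise intersection total |set_i  ∩ set_j|
.pairTotal <- function(card, i, j) {
  has <- vapply(names(card@counts), function(k) {
    ki <- .keyIndices(k); (i %in% ki) && (j %in% ki)
  }, logical(1))
  sum(card@counts[has])
}

#' Seeded random set-collection generator
#'
#' Test-fixture generator: each of `universeSize` elements ("e1", "e2", ...)
#' joins each of `nSets` sets independently with probability `membershipProb`.
#' The same seed always yields the same collection; the caller's random-number
#' state is left untouched.
#'
#' @param nSets Number of sets (1 to 4).
#' @param universeSize Number of candidate elements (>= 1).
#' @param membershipProb Membership probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [SetCollection-class] with labels "A", "B", "C", "D".
#' @examples
#' generateRandomSets(2, 20, 0.5, seed = 7)
#' @export
generateRandomSets <- function(nSets, universeSize, membershipProb, seed) {
  nSets <- .checkN(nSets)
  if (length(universeSize) != 1L || is.na(universeSize) || universeSize < 1 ||
      universeSize != as.integer(universeSize))
    .vfError("invalidInputError", "universeSize must be a positive integer")
  if (length(membershipProb) != 1L || is.na(membershipProb) ||
      membershipProb < 0 || membershipProb > 1)
    .vfError("invalidInputError", "membershipProb must be in [0, 1]")
  elements <- paste0("e", seq_len(universeSize))
  sets <- .withSeed(seed, {
    lapply(seq_len(nSets), function(i)
      elements[stats::runif(universeSize) < membershipProb])
  })
  names(sets) <- c("A", "B", "C", "D")[seq_len(nSets)]
  new("SetCollection", setLabels = names(sets),
      members = unname(lapply(sets, as.character)))
}

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
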