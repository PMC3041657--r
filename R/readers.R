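#' @include setAlgebra.R
NULL

.checkReadable <- function(paths) {
  bad <- paths[!file.exists(paths)]
  if (length(bad))
    .vfError("ioError", paste("input file(s) not found:",
                              paste(bad, collapse = ", ")))
  invisible(paths)
}

#' Read sets from one-element-per-line list files
#'
#' Each file contributes one set: UTF-8 text, one element identifier per line,
#' blank lines ignored, leading/trailing whitespace trimmed.  The set label is
#' the file name without its extension.
#'
#' @param paths Character vector of 1 to 4 file paths.
#' @return A [SetCollection-class].
#' @export
readSetLists <- function(paths) {
  if (length(paths) < 1L)
    .vfError("invalidInputError", "at least one list file is required")
  if (length(paths) > 4L)
    .vfError("unsupportedSizeError", sprintf(
      "diagrams support 1 to 4 sets, got %d list files", length(paths)))
  .checkReadable(paths)
  sets <- lapply(paths, function(p) {
    x <- trimws(readLines(p, encoding = "UTF-8", warn = FALSE))
    x[nzchar(x)]
  })
  names(sets) <- tools::file_path_sans_ext(basename(paths))
  SetCollection(sets)
}

#' Read sets from a two-column delimited table
#'
#' The file has a header and two columns, set name and element identifier,
#' one membership per row.  The delimiter is auto-detected (tab or comma)
#' unless given.
#'
#' @param path Path of the table file.
#' @param sep Field separator; `NULL` (default) tries tab, then comma.
#' @return A [SetCollection-class]; set order follows first appearance.
#' @export
readSetTable <- function(path, sep = NULL) {
  .checkReadable(path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    .vfError("invalidInputError",
             "set table must have two columns: set name, element")
  labs <- unique(df[[1L]])
  if (length(labs) > 4L)
    .vfError("unsupportedSizeError", sprintf(
      "diagrams support 1 to 4 sets, table names %d", length(labs)))
  sets <- lapply(labs, function(l) df[[2L]][df[[1L]] == l])
  names(sets) <- labs
  SetCollection(sets)
}

#' Read sets from a JSON mapping
#'
#' The document is a JSON object mapping each set name to an array of element
#' strings: `{"A": ["x", "y"], "B": ["y"]}`.
#'
#' @param path Path of the JSON file.
#' @return A [SetCollection-class].
#' @export
readSetJSON <- function(path) {
  .checkReadable(path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(obj) || is.null(names(obj)))
    .vfError("invalidInputError",
             "JSON sets file must be an object mapping set name -> array")
  SetCollection(lapply(obj, as.character))
}

#' Read a region-count table from JSON
#'
#' Two layouts are accepted:
#' \itemize{
#'   \item `{"sets": ["A","B"], "counts": {"A": 5, "A&B": 2}}` — region keys
#'     are set names joined by `&`; omitted regions count zero.
#'   \item a flat object keyed by canonical index strings:
#'     `{"1": 5, "12": 2}`.
#' }
#'
#' @param path Path of the JSON file.
#' @return A validated [RegionCardinalities-class].
#' @export
readCardinalitiesJSON <- function(path) {
  .checkReadable(path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(obj$sets) && !is.null(obj$counts)) {
    labs <- as.character(obj$sets)
    if (length(labs) < 1L || anyDuplicated(labs))
      .vfError("invalidInputError", "\"sets\" must list distinct set names")
    if (length(labs) > 4L)
      .vfError("unsupportedSizeError", sprintf(
        "diagrams support 1 to 4 sets, got %d", length(labs)))
    cnt <- unlist(obj$counts)
    keys <- vapply(names(cnt), function(k) {
      parts <- trimws(strsplit(k, "&", fixed = TRUE)[[1L]])
      i <- match(parts, labs)
      if (anyNA(i))
        .vfError("invalidInputError", sprintf(
          "region \"%s\" names a set absent from \"sets\"", k))
      paste(sort(i), collapse = "")
    }, character(1))
    names(cnt) <- keys
    validateCardinalities(cnt, nSets = length(labs), setLabels = labs)
  } else {
    validateCardinalities(unlist(obj))
  }
}
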