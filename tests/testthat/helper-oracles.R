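# Independent brute-force oracle: tally each element's membership bit-vector
# without using the package's region machinery.
bruteForceRegions <- function(members) {
  n <- length(members)
  keys <- character(0)
  for (size in seq_len(n))
    keys <- c(keys, apply(utils::combn(n, size), 2L, paste, collapse = ""))
  counts <- stats::setNames(numeric(length(keys)), keys)
  universe <- unique(unlist(members, use.names = FALSE))
  for (el in universe) {
    inSets <- which(vapply(members, function(m) el %in% m, logical(1)))
    if (length(inSets))
      counts[paste(inSets, collapse = "")] <-
        counts[paste(inSets, collapse = "")] + 1
  }
  counts
}

# Region table straight from a zero/nonzero pattern (1 element per occupied
# region); bypasses validation so the all-zero pattern is constructible.
cardFromPattern <- function(pattern, n) {
  counts <- stats::setNames(as.numeric(pattern), regionKeys(n))
  methods::new("RegionCardinalities", nSets = as.integer(n), counts = counts,
               setLabels = c("A", "B", "C", "D")[seq_len(n)])
}

# Monte-Carlo standard error of an estimated region area
mcAreaSE <- function(oracle, key) {
  p <- oracle$hits[[key]] / oracle$nSamples
  oracle$boxArea * sqrt(p * (1 - p) / oracle$nSamples)
}

# all text labels printed by a figure grob (area labels, captions, titles)
grobTexts <- function(grob) {
  unlist(lapply(grob$children, function(g)
    if (inherits(g, "text")) as.character(g$label) else character(0)))
}

fastStyle <- function(...) DiagramStyle(samples = 2e4, ...)

.newLayoutForTest <- function(shapes)
  methods::new("VennLayout", shapes = shapes,
               diagramClass = paste0("VENN_", length(shapes)),
               regionAnchors = list(), regionLabels = character(0),
               captionAnchors = list(), leaderLines = list(),
               setLabels = LETTERS[seq_along(shapes)])
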