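#' @include AllClasses.R
NULL

.lineTypes <- c("solid", "dashed", "dotted", "dotdash", "longdash",
                "twodash", "blank")
.fontFaces <- c("plain", "bold", "italic", "bold.italic")
.captionModes <- c("default", "text", "explicit")
.justValues <- c("auto", "left", "right", "centre", "center")

.isColor <- function(x) {
  vapply(x, function(v)
    is.character(v) && length(v) == 1L && !is.na(v) &&
      (v %in% grDevices::colours() || grepl("^#[0-9a-fA-F]{6}([0-9a-fA-F]{2})?$", v)),
    logical(1))
}

.styleError <- function(key, why)
  .vfError("configError", sprintf("invalid style value for \"%s\": %s", key, why))

## json key -> list(slot, check(value, key) -> coerced value)
.styleSchema <- function() {
  num01 <- function(v, k) {
    v <- suppressWarnings(as.numeric(v))
    if (anyNA(v) || any(v < 0) || any(v > 1)) .styleError(k, "must be in [0, 1]")
    v
  }
  pos <- function(v, k) {
    v <- suppressWarnings(as.numeric(v))
    if (anyNA(v) || any(v <= 0)) .styleError(k, "must be positive")
    v
  }
  colr <- function(v, k) {
    v <- as.character(v)
    if (!all(.isColor(v)))
      .styleError(k, "unknown color (use an R color name or #RRGGBB[AA])")
    v
  }
  choice <- function(set) function(v, k) {
    v <- as.character(v)
    if (!all(v %in% set))
      .styleError(k, paste("must be one of", paste(set, collapse = ", ")))
    v
  }
  chr <- function(v, k) as.character(v)
  one <- function(f) function(v, k) {
    v <- f(v, k)
    if (length(v) != 1L) .styleError(k, "must be a single value")
    v
  }
  bool <- function(v, k) {
    if (!is.logical(v) || length(v) != 1L || is.na(v))
      .styleError(k, "must be true or false")
    v
  }
  realv <- function(v, k) {
    v <- suppressWarnings(as.numeric(v))
    if (anyNA(v) || any(!is.finite(v))) .styleError(k, "must be finite")
    v
  }
  xy <- function(v, k) {
    v <- suppressWarnings(as.numeric(unlist(v)))
    if (length(v) != 2L || anyNA(v)) .styleError(k, "must be a pair (x, y)")
    v
  }
  list(
    fill = list("fill", colr),
    alpha = list("alpha", num01),
    line_style = list("lineStyle", choice(.lineTypes)),
    line_width = list("lineWidth", pos),
    line_color = list("lineColor", colr),
    label_font_family = list("labelFontFamily", one(chr)),
    label_font_face = list("labelFontFace", one(choice(.fontFaces))),
    label_size = list("labelSize", one(pos)),
    label_color = list("labelColor", one(colr)),
    caption_text = list("captionText", chr),
    caption_font_family = list("captionFontFamily", one(chr)),
    caption_font_face = list("captionFontFace", one(choice(.fontFaces))),
    caption_size = list("captionSize", one(pos)),
    caption_color = list("captionColor", one(colr)),
    caption_mode = list("captionMode", one(choice(.captionModes))),
    caption_positions = list("captionPositions", function(v, k) {
      m <- try({
        if (is.matrix(v)) matrix(as.numeric(v), ncol = ncol(v))
        else if (is.list(v)) do.call(rbind, lapply(v, as.numeric))
        else matrix(as.numeric(v), ncol = 2L, byrow = TRUE)
      }, silent = TRUE)
      if (inherits(m, "try-error") || !is.matrix(m) || ncol(m) != 2L || anyNA(m))
        .styleError(k, "must be an array of [x, y] pairs")
      m
    }),
    caption_just = list("captionJust", one(choice(.justValues))),
    caption_distance = list("captionDistance", one(pos)),
    main_title = list("mainTitle", one(chr)),
    subtitle = list("subTitle", one(chr)),
    title_font_family = list("titleFontFamily", one(chr)),
    title_font_face = list("titleFontFace", one(choice(.fontFaces))),
    title_size = list("titleSize", one(pos)),
    title_color = list("titleColor", one(colr)),
    title_position = list("titlePosition", xy),
    subtitle_position = list("subtitlePosition", xy),
    margin = list("margin", function(v, k) {
      v <- one(realv)(v, k)
      if (v < 0 || v > 0.45) .styleError(k, "must be in [0, 0.45]")
      v
    }),
    rotation = list("rotation", one(realv)),
    invert = list("invert", bool),
    euler = list("eulerEnabled", bool),
    scaled = list("scaled", bool),
    small_region_threshold = list("smallRegionThreshold", one(pos)),
    tangency_gap = list("tangencyGap", one(pos)),
    min_radius = list("minRadius", one(pos)),
    samples = list("samples", function(v, k) {
      v <- one(pos)(v, k)
      if (v < 1e4) .styleError(k, "must be at least 10000")
      v
    }),
    oracle_seed = list("oracleSeed", one(realv))
  )
}

#' Construct a DiagramStyle
#'
#' All arguments are optional; the defaults produce sensible diagrams without
#' customization (white background, distinct semi-transparent fills, solid
#' black outlines, sans-serif labels).  Arguments are named by the JSON
#' configuration keys (see [parseStyle()]); values are validated the same way.
#'
#' @param ... Style settings, e.g. `fill = c("red", "blue")`, `alpha = 0.4`,
#'   `scaled = TRUE`, `rotation = 90`.
#' @return A validated [DiagramStyle-class].
#' @examples
#' DiagramStyle(scaled = TRUE, main_title = "Overlap")
#' @export
DiagramStyle <- function(...) {
  style <- new("DiagramStyle",
    fill = c("#4477AA", "#EE6677", "#228833", "#CCBB44"), alpha = 0.5,
    lineStyle = "solid", lineWidth = 2, lineColor = "black",
    labelFontFamily = "sans", labelFontFace = "plain",
    labelSize = 0.025, labelColor = "black",
    captionText = character(0),
    captionFontFamily = "sans", captionFontFace = "plain",
    captionSize = 0.03, captionColor = "black",
    captionMode = "default",
    captionPositions = matrix(numeric(0), ncol = 2L),
    captionJust = "auto", captionDistance = 0.05,
    mainTitle = "", subTitle = "",
    titleFontFamily = "sans", titleFontFace = "bold",
    titleSize = 0.04, titleColor = "black",
    titlePosition = c(0.5, 0.97), subtitlePosition = c(0.5, 0.93),
    margin = 0.05, rotation = 0, invert = FALSE,
    eulerEnabled = TRUE, scaled = FALSE,
    smallRegionThreshold = 0.04, tangencyGap = 0.01, minRadius = 0.02,
    samples = 1e5, oracleSeed = 20110126)
  updateStyle(style, list(...))
}

#' Update a style with a named list of JSON-keyed settings
#'
#' @param style A [DiagramStyle-class].
#' @param settings Named list; unknown keys are skipped with a warning,
#'   invalid values raise a `configError` naming the key.
#' @return The updated [DiagramStyle-class].
#' @export
updateStyle <- function(style, settings) {
  if (length(settings) == 0L) return(style)
  schema <- .styleSchema()
  if (is.null(names(settings)) || any(!nzchar(names(settings))))
    .vfError("configError", "style settings must be named")
  for (key in names(settings)) {
    entry <- schema[[key]]
    if (is.null(entry)) {
      .vfWarn("unknownStyleKeyWarning",
              sprintf("unknown style key \"%s\" ignored", key))
      next
    }
    methods::slot(style, entry[[1]]) <- entry[[2]](settings[[key]], key)
  }
  methods::validObject(style)
  style
}

setValidity("DiagramStyle", function(object) {
  if (any(object@alpha < 0 | object@alpha > 1)) return("alpha must be in [0, 1]")
  if (any(object@lineWidth <= 0)) return("line width must be positive")
  if (object@labelSize <= 0 || object@captionSize <= 0 || object@titleSize <= 0)
    return("font sizes must be positive")
  if (!all(object@lineStyle %in% .lineTypes)) return("unknown line style")
  if (!is.finite(object@rotation)) return("rotation must be finite")
  TRUE
})

#' Parse a JSON style configuration
#'
#' Missing keys keep their documented defaults; unknown keys produce a warning
#' and are ignored; invalid values raise a `configError` naming the offending
#' key.  The schema (all keys optional): `fill`, `alpha`, `line_style`,
#' `line_width`, `line_color`, `label_font_family`, `label_font_face`,
#' `label_size`, `label_color`, `caption_text`, `caption_font_family`,
#' `caption_font_face`, `caption_size`, `caption_color`, `caption_mode`,
#' `caption_positions`, `caption_just`, `caption_distance`, `main_title`,
#' `subtitle`, `title_font_family`, `title_font_face`, `title_size`,
#' `title_color`, `title_position`, `subtitle_position`, `margin`, `rotation`,
#' `invert`, `euler`, `scaled`, `small_region_threshold`, `tangency_gap`,
#' `min_radius`, `samples`, `oracle_seed`.
#'
#' @param config A path to a JSON file, a JSON string, a named list, or
#'   `NULL`/empty for the full default configuration.
#' @return A validated [DiagramStyle-class].
#' @examples
#' parseStyle('{"alpha": 0.4, "line_style": "blank"}')
#' @export
parseStyle <- function(config = NULL) {
  if (is.null(config) || (is.character(config) && !nzchar(trimws(config)[1])))
    return(DiagramStyle())
  if (is(config, "DiagramStyle")) return(config)
  if (is.character(config)) {
    txt <- if (file.exists(config)) paste(readLines(config, warn = FALSE),
                                          collapse = "\n") else config
    obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                    error = function(e) .vfError("configError", paste(
                      "style configuration is not valid JSON:",
                      conditionMessage(e))))
  } else if (is.list(config)) {
    obj <- config
  } else {
    .vfError("configError", "config must be a JSON document or a named list")
  }
  updateStyle(DiagramStyle(), as.list(obj))
}

#' Serialize a style back to its JSON configuration
#'
#' The output parses back to an identical style:
#' `parseStyle(styleToJSON(style))` equals `style`.
#'
#' @param style A [DiagramStyle-class].
#' @return A JSON string.
#' @export
styleToJSON <- function(style) {
  stopifnot(is(style, "DiagramStyle"))
  schema <- .styleSchema()
  out <- list()
  for (key in names(schema)) {
    v <- methods::slot(style, schema[[key]][[1]])
    if (is.matrix(v)) {
      if (nrow(v) == 0L) next
      v <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    }
    if (length(v) == 0L) next
    out[[key]] <- v
  }
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
}
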