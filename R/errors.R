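## Classed conditions so callers (and the command-line wrapper) can map each
## failure mode to a distinct handler / exit code.

.vfError <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "vennForgeError")))
}

.vfWarn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "vennForgeWarning")))
}

#' Error classes used by VennForge
#'
#' All errors signalled by the package carry the class `vennForgeError` plus
#' one of the specific classes below, so they can be caught selectively with
#' [tryCatch()]:
#'
#' \describe{
#'   \item{`invalidInputError`}{malformed sets, negative counts, bad parameters.}
#'   \item{`unsupportedSizeError`}{more than four sets (or fewer than one).}
#'   \item{`emptyDiagramError`}{every region count is zero.}
#'   \item{`infeasibleOverlapError`}{a requested intersection area exceeds the
#'     smaller circle, so no center distance can realize it.}
#'   \item{`unrealizableArrangementError`}{pairwise distances solved from the
#'     intersection areas violate the triangle inequality.}
#'   \item{`unsupportedScalingError`}{area-proportional scaling requested for a
#'     three- or four-set Venn diagram, where circle geometry does not
#'     determine a unique layout.}
#'   \item{`wrongClassError`}{a layout routine was handed a diagram class it
#'     does not implement.}
#'   \item{`configError`}{an invalid value in a style configuration.}
#'   \item{`formatError`}{an unsupported output format.}
#'   \item{`ioError`}{an unwritable or unreadable path.}
#' }
#'
#' @name vennforge-errors
#' @keywords internal
NULL
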