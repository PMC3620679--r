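#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
NULL

#' Recombination map of fixed-width windows with standardized rates
#'
#' A \code{RecombMap} is a \code{\linkS4class{GRanges}} whose ranges are the
#' map windows (typically tiling each autosome at a fixed resolution such as
#' 10 kb) and whose metadata column \code{srr} holds the standardized
#' recombination rate of each window: the window's rate divided by the
#' genome-wide average, so a value of 1 means an average window and values
#' above 10 mark recombination hotspots.
#'
#' Windows within one chromosome share a single fixed width, except possibly
#' the last window where the chromosome length is not divisible by the
#' resolution.
#'
#' @seealso [readRecombMap()], [classifySpots()]
#' @exportClass RecombMap
setClass("RecombMap", contains = "GRanges")

setValidity("RecombMap", function(object) {
  msg <- NULL
  if (!"srr" %in% colnames(mcols(object)))
    msg <- c(msg, "metadata column 'srr' is required")
  else {
    srr <- mcols(object)$srr
    if (!is.numeric(srr))
      msg <- c(msg, "'srr' must be numeric")
    else if (any(!is.finite(srr)) || any(srr < 0))
      msg <- c(msg, "'srr' must be finite and >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a RecombMap
#'
#' @param windows a \code{GRanges} of map windows (or a \code{RecombMap}).
#' @param srr numeric vector of standardized recombination rates, one per
#'   window; if missing, \code{windows} must already carry an \code{srr}
#'   metadata column.
#' @return a sorted \code{RecombMap}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
#' RecombMap(gr, srr = 12.5)
#' @export
RecombMap <- function(windows, srr) {
  if (!is(windows, "GRanges"))
    stop("'windows' must be a GRanges")
  if (!missing(srr))
    mcols(windows)$srr <- as.numeric(srr)
  obj <- as(sort(windows, ignore.strand = TRUE), "RecombMap")
  validObject(obj)
  obj
}

#' @describeIn RecombMap standardized recombination rate accessor.
#' @param x a \code{RecombMap}.
#' @export
srr <- function(x) {
  stopifnot(is(x, "GRanges"))
  mcols(x)$srr
}

setMethod("show", "RecombMap", function(object) {
  cat(sprintf("RecombMap with %d windows on %d sequence(s)\n",
              length(object), length(unique(as.character(seqnames(object))))))
  if (length(object)) {
    cat(sprintf("  window width: %s; SRR range: [%.3g, %.3g]\n",
                paste(unique(head(width(object), 1000L)), collapse = "/"),
                min(srr(object)), max(srr(object))))
  }
  invisible(callNextMethod())
})

.SPOT_LABELS <- c("hot", "middle", "cold")

#' A labelled set of recombination spots
#'
#' A \code{SpotSet} is a \code{\linkS4class{GRanges}} of map windows that
#' passed one SRR classification rule, tagged with the rule's label:
#' \code{"hot"} (SRR above the hotspot threshold), \code{"middle"}
#' (intermediate SRR) or \code{"cold"} (SRR equal to the cold value).
#' Each passing window is one spot; contiguous passing windows are not
#' merged, so spot counts are in units of map windows.
#'
#' @slot label one of \code{"hot"}, \code{"middle"}, \code{"cold"}.
#' @seealso [classifySpots()], [sampleSpots()]
#' @exportClass SpotSet
setClass("SpotSet", contains = "GRanges",
         representation(label = "character"))

setValidity("SpotSet", function(object) {
  msg <- NULL
  if (length(object@label) != 1L || !object@label %in% .SPOT_LABELS)
    msg <- c(msg, "'label' must be one of \"hot\", \"middle\", \"cold\"")
  if (any(duplicated(object)))
    msg <- c(msg, "duplicate spot intervals are not allowed")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SpotSet
#'
#' @param spots a \code{GRanges} of spot intervals.
#' @param label spot class label: \code{"hot"}, \code{"middle"} or
#'   \code{"cold"}.
#' @return a sorted \code{SpotSet}.
#' @export
SpotSet <- function(spots, label) {
  if (!is(spots, "GRanges"))
    stop("'spots' must be a GRanges")
  obj <- new("SpotSet", sort(spots, ignore.strand = TRUE),
             label = as.character(label))
  validObject(obj)
  obj
}

#' @describeIn SpotSet spot class label accessor.
#' @param x a \code{SpotSet}.
#' @export
spotLabel <- function(x) {
  stopifnot(is(x, "SpotSet"))
  x@label
}

setMethod("show", "SpotSet", function(object) {
  cat(sprintf("SpotSet <%s> with %d spots\n", object@label, length(object)))
  invisible(callNextMethod())
})
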