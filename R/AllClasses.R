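#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' PeakSet: one cell line's peak or cluster track
#'
#' A `PeakSet` bundles the intervals called in one assay track (H3K27ac
#' peaks, DNase clusters, TF ChIP-seq clusters, ...) for one cell line or
#' tissue, as a [GenomicRanges::GRanges] plus track identity. Readers may
#' merge overlapping input intervals; the number of intervals seen before
#' merging is retained in `preMergeCount`.
#'
#' @slot sampleId character(1), cell-line or tissue label.
#' @slot mark character(1), assay label (e.g. `"H3K27ac"`, `"DNase"`, or a
#'   transcription-factor name).
#' @slot ranges a `GRanges` with the intervals, sorted by coordinate.
#'   Optional metadata columns `name` and `score` hold BED columns 4-5.
#' @slot preMergeCount integer(1), interval count before any merging.
#'
#' @seealso [readBed()], [mergeIntervals()], [coverageStack()]
#' @export
setClass("PeakSet",
  representation(
    sampleId = "character",
    mark = "character",
    ranges = "GRanges",
    preMergeCount = "integer"
  ),
  prototype(
    sampleId = NA_character_,
    mark = NA_character_,
    preMergeCount = 0L
  )
)

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(object@mark) != 1L)
    msg <- c(msg, "mark must be a single string")
  if (length(object@preMergeCount) != 1L || is.na(object@preMergeCount) ||
      object@preMergeCount < 0L)
    msg <- c(msg, "preMergeCount must be a single non-negative integer")
  o <- GenomicRanges::order(object@ranges)
  if (length(o) && any(diff(o) < 0L))
    msg <- c(msg, "ranges must be coordinate-sorted")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param ranges a `GRanges` (strand is ignored throughout the package).
#' @param sampleId cell-line or tissue label.
#' @param mark assay label.
#' @param merge merge overlapping and adjacent intervals (the default for
#'   signal tracks such as H3K27ac). Use `merge = FALSE` for tracks whose
#'   rows carry identities that must survive, e.g. named TF clusters.
#' @param preMergeCount interval count before merging; defaults to
#'   `length(ranges)`.
#' @return a [PeakSet-class] object.
#' @export
PeakSet <- function(ranges, sampleId = NA_character_, mark = NA_character_,
                    merge = TRUE, preMergeCount = length(ranges)) {
  stopifnot(is(ranges, "GRanges"))
  GenomicRanges::strand(ranges) <- "*"
  ranges <- GenomicRanges::sort(ranges)
  if (merge) ranges <- mergeIntervals(ranges)
  new("PeakSet",
    sampleId = as.character(sampleId), mark = as.character(mark),
    ranges = ranges, preMergeCount = as.integer(preMergeCount))
}

#' @describeIn PeakSet-class intervals as a `GRanges`.
#' @param x,object a `PeakSet`.
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname PeakSet-class
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@ranges)

#' @describeIn PeakSet-class cell-line / tissue label.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname PeakSet-class
#' @export
setMethod("sampleId", "PeakSet", function(x) x@sampleId)

#' @describeIn PeakSet-class assay label.
#' @export
setGeneric("peakMark", function(x) standardGeneric("peakMark"))

#' @rdname PeakSet-class
#' @export
setMethod("peakMark", "PeakSet", function(x) x@mark)

#' @describeIn PeakSet-class interval count before merging.
#' @export
setGeneric("preMergeCount", function(x) standardGeneric("preMergeCount"))

#' @rdname PeakSet-class
#' @export
setMethod("preMergeCount", "PeakSet", function(x) x@preMergeCount)

#' @rdname PeakSet-class
#' @export
setMethod("length", "PeakSet", function(x) length(x@ranges))

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", object@sampleId, "/", object@mark, "\n")
  cat(" ", length(object@ranges), "intervals (", object@preMergeCount,
      "before merge )\n")
  if (length(object@ranges))
    show(utils::head(object@ranges, 3L))
})

#' ScreenConfig: parameters of the consensus enhancer screen
#'
#' Holds the tunable thresholds of the H3K27ac consensus screen and the
#' anchor transcription start site used for proximal/distal classification.
#'
#' @slot minSupportFraction numeric in (0, 1]; minimum fraction of the
#'   FAP-positive peak sets whose peaks must stack on a region before it is
#'   called. Default 0.75, tolerating dropout of one line in four.
#' @slot maxNegativeHits integer >= 0; maximum number of FAP-negative peak
#'   sets allowed to overlap a surviving candidate. Default 0 ("absent in
#'   negative lines").
#' @slot tss `GRanges` of length 1 (or NULL before it is set), the anchor
#'   transcription start site of the regulated gene.
#' @slot proximalWindow integer > 0, bp; candidates within this distance of
#'   the TSS are classed `proximal` (promoter territory), the rest `distal`.
#'   Default 3000 bp.
#' @slot minWidth integer, bp; consensus regions narrower than this are
#'   discarded. Default 200 bp.
#' @slot mergeGap integer, bp; gaps up to this size between consensus
#'   pieces are closed. Default 500 bp.
#'
#' @export
setClass("ScreenConfig",
  representation(
    minSupportFraction = "numeric",
    maxNegativeHits = "integer",
    tss = "GRangesOrNULL",
    proximalWindow = "integer",
    minWidth = "integer",
    mergeGap = "integer"
  ),
  prototype(
    minSupportFraction = 0.75,
    maxNegativeHits = 0L,
    tss = NULL,
    proximalWindow = 3000L,
    minWidth = 200L,
    mergeGap = 500L
  )
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (length(object@minSupportFraction) != 1L ||
      object@minSupportFraction <= 0 || object@minSupportFraction > 1)
    msg <- c(msg, "minSupportFraction must be in (0, 1]")
  if (object@maxNegativeHits < 0L)
    msg <- c(msg, "maxNegativeHits must be >= 0")
  if (object@proximalWindow <= 0L)
    msg <- c(msg, "proximalWindow must be > 0")
  if (object@minWidth < 0L)
    msg <- c(msg, "minWidth must be >= 0")
  if (object@mergeGap < 0L)
    msg <- c(msg, "mergeGap must be >= 0")
  if (!is.null(object@tss) && length(object@tss) != 1L)
    msg <- c(msg, "tss must be a single range")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenConfig
#'
#' @param minSupportFraction,maxNegativeHits,tss,proximalWindow,minWidth,mergeGap
#'   see [ScreenConfig-class] for meaning, units and defaults.
#' @return a [ScreenConfig-class] object.
#' @examples
#' cfg <- ScreenConfig(tss = GenomicRanges::GRanges("chr2", IRanges::IRanges(50000, 50000)))
#' @export
ScreenConfig <- function(minSupportFraction = 0.75, maxNegativeHits = 0L,
                         tss = NULL, proximalWindow = 3000L,
                         minWidth = 200L, mergeGap = 500L) {
  new("ScreenConfig",
    minSupportFraction = as.numeric(minSupportFraction),
    maxNegativeHits = as.integer(maxNegativeHits),
    tss = tss,
    proximalWindow = as.integer(proximalWindow),
    minWidth = as.integer(minWidth),
    mergeGap = as.integer(mergeGap))
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig\n")
  cat("  minSupportFraction:", object@minSupportFraction, "\n")
  cat("  maxNegativeHits:   ", object@maxNegativeHits, "\n")
  cat("  proximalWindow:    ", object@proximalWindow, "bp\n")
  cat("  minWidth / mergeGap:", object@minWidth, "/", object@mergeGap, "bp\n")
  if (!is.null(object@tss)) {
    cat("  tss: ")
    cat(as.character(GenomicRanges::seqnames(object@tss)), ":",
        GenomicRanges::start(object@tss), "\n", sep = "")
  } else cat("  tss: <unset>\n")
})
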