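#' Total number of tag events in an index
#' @param x a [TagIndex-class] or [BinCounts-class]
#' @return a single number
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' Chromosome sizes of an object
#' @param x an object carrying chromosome sizes
#' @return named integer vector of chromosome lengths (bp)
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' Event positions stored in a TagIndex
#' @param x a [TagIndex-class]
#' @param chrom optional chromosome name; if omitted the full named list
#' @return integer vector (one chromosome) or named list of integer vectors
#' @export
setGeneric("tagPositions", function(x, chrom = NULL) standardGeneric("tagPositions"))

#' Number of events clamped to chromosome bounds during shifting
#' @param x a [TagIndex-class]
#' @return integer
#' @export
setGeneric("clampedCount", function(x) standardGeneric("clampedCount"))

#' Offsets of a signal profile
#' @param x a [SignalProfile-class]
#' @return integer vector of offsets (bp)
#' @export
setGeneric("profileOffsets", function(x) standardGeneric("profileOffsets"))

#' Values of a signal profile
#' @param x a [SignalProfile-class]
#' @return numeric vector of per-offset mean net tag counts
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Correlation coefficient matrix
#' @param x a [MarkCorrelation-class]
#' @return symmetric numeric matrix
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname totalCount
#' @export
setMethod("totalCount", "TagIndex", function(x) sum(lengths(x@positions)))

#' @rdname totalCount
#' @export
setMethod("totalCount", "BinCounts", function(x) sum(vapply(x@counts, sum, numeric(1))))

#' @rdname chromSizes
#' @export
setMethod("chromSizes", "TagIndex", function(x) x@chromSizes)

#' @rdname chromSizes
#' @export
setMethod("chromSizes", "BinCounts", function(x) x@chromSizes)

#' @rdname tagPositions
#' @export
setMethod("tagPositions", "TagIndex", function(x, chrom = NULL) {
  if (is.null(chrom)) return(x@positions)
  if (!chrom %in% names(x@positions)) return(integer(0))
  x@positions[[chrom]]
})

#' @rdname clampedCount
#' @export
setMethod("clampedCount", "TagIndex", function(x) x@nClamped)

#' @rdname profileOffsets
#' @export
setMethod("profileOffsets", "SignalProfile", function(x) x@offsets)

#' @rdname profileValues
#' @export
setMethod("profileValues", "SignalProfile", function(x) x@values)

#' @rdname corMatrix
#' @export
setMethod("corMatrix", "MarkCorrelation", function(x) x@matrix)

setMethod("show", "TagIndex", function(object) {
  cat(sprintf("TagIndex [%s]: %d events on %d chromosome(s), %d clamped\n",
              object@source, totalCount(object), length(object@chromSizes),
              object@nClamped))
})

setMethod("show", "BinCounts", function(object) {
  cat(sprintf("BinCounts: %d-bp bins, %d chromosome(s), %.0f events\n",
              object@binSize, length(object@counts), totalCount(object)))
})

setMethod("show", "SignalProfile", function(object) {
  cat(sprintf(
    "SignalProfile: offsets %d..%d, %d sites, smoothing %d bp, %soriented\n",
    min(object@offsets), max(object@offsets), object@nSites,
    object@smoothing, if (object@oriented) "" else "not "))
})

setMethod("show", "ProfileShape", function(object) {
  cat(sprintf(
    "ProfileShape: %d mode(s) at {%s}, inter-peak %s bp, asymmetry %.3f, min at %d bp\n",
    object@nModes, paste(object@modeOffsets, collapse = ", "),
    if (is.na(object@interPeakDistance)) "NA" else
      format(object@interPeakDistance), object@asymmetryIndex,
    object@minOffset))
})

setMethod("show", "MarkCorrelation", function(object) {
  cat(sprintf("MarkCorrelation [%s]: %d marks, n = %d\n", object@context,
              nrow(object@matrix), object@nObs))
  print(round(object@matrix, 3))
})
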