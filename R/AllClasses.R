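#' @import methods
#' @importFrom stats median rnorm rpois runif rgamma rlnorm cor wilcox.test
#'   ppois qpois pbinom dpois setNames
#' @importFrom utils head tail
NULL

# Coordinate convention used throughout the package:
#  * on disk, tag/peak intervals are BED: 0-based, half-open.
#  * in memory, tag intervals are GRanges (1-based, closed), converted at I/O.
#  * point coordinates (site positions, TSSs, shifted tag events, profile
#    offsets) are 0-based base positions, matching BED arithmetic.

#' TagIndex: positional tag events ready for counting
#'
#' A `TagIndex` stores, per chromosome, the sorted 0-based genomic positions of
#' tag events (typically the 5' ends of sequenced ChIP fragments after the
#' standard 100-bp shift towards the fragment centre), together with the
#' chromosome sizes, a source label and the number of events that had to be
#' clamped to chromosome bounds during shifting.
#'
#' @slot positions named list, one sorted integer vector of 0-based event
#'   positions per chromosome.
#' @slot chromSizes named integer vector of chromosome lengths (bp).
#' @slot source single character, `"mark"` or `"control"` (free text allowed).
#' @slot nClamped integer, number of events clamped to chromosome bounds.
#'
#' @seealso [shiftTags()], [countWindow()], [binCounts()]
#' @export
setClass("TagIndex",
  representation(positions = "list", chromSizes = "integer",
                 source = "character", nClamped = "integer"))

setValidity("TagIndex", function(object) {
  msg <- character()
  cs <- object@chromSizes
  if (is.null(names(cs)) || any(!nzchar(names(cs))))
    msg <- c(msg, "chromSizes must be named")
  if (any(cs <= 0L)) msg <- c(msg, "chromosome lengths must be positive")
  if (!all(names(object@positions) %in% names(cs)))
    msg <- c(msg, "positions on chromosomes absent from chromSizes")
  for (chr in names(object@positions)) {
    p <- object@positions[[chr]]
    if (is.unsorted(p)) msg <- c(msg, sprintf("positions on %s not sorted", chr))
    if (length(p) && (p[1L] < 0L || p[length(p)] >= cs[[chr]]))
      msg <- c(msg, sprintf("positions on %s out of bounds", chr))
  }
  if (length(msg)) msg else TRUE
})

#' BinCounts: tag counts over a non-overlapping genome grid
#'
#' Counts of tag events in consecutive, non-overlapping bins covering each
#' chromosome (the last bin of a chromosome may be truncated).  Used for
#' genome-wide mark-mark correlation.
#'
#' @slot binSize integer, bin width in bp.
#' @slot counts named list, one integer vector of per-bin counts per
#'   chromosome, of length `ceiling(chromLength / binSize)`.
#' @slot chromSizes named integer vector of chromosome lengths.
#' @export
setClass("BinCounts",
  representation(binSize = "integer", counts = "list", chromSizes = "integer"))

setValidity("BinCounts", function(object) {
  msg <- character()
  if (object@binSize <= 0L) msg <- c(msg, "binSize must be positive")
  cs <- object@chromSizes
  if (!identical(sort(names(object@counts)), sort(names(cs))))
    msg <- c(msg, "counts and chromSizes name mismatch")
  for (chr in names(object@counts)) {
    want <- as.integer(ceiling(cs[[chr]] / object@binSize))
    if (length(object@counts[[chr]]) != want)
      msg <- c(msg, sprintf("wrong number of bins on %s", chr))
    if (any(object@counts[[chr]] < 0L)) msg <- c(msg, "negative bin count")
  }
  if (length(msg)) msg else TRUE
})

#' SignalProfile: average (net) tag signal around a set of anchors
#'
#' Per-offset average tag count around a site set, after optional per-position
#' control subtraction, optional strand orientation (profiles of sites
#' assigned to minus-strand genes are mirrored before averaging) and optional
#' moving-average smoothing.  `support` records, per offset, how many sites
#' contributed a defined position (sites near chromosome ends contribute only
#' their in-bounds offsets).
#'
#' @slot offsets integer vector of offsets (bp) relative to the anchor,
#'   typically `-flank:flank`.
#' @slot values numeric vector, mean net tag count per position per site.
#' @slot support numeric vector, per-offset number of contributing sites.
#' @slot nSites integer, number of anchors aggregated.
#' @slot smoothing integer, moving-average window in bp (0 = unsmoothed).
#' @slot oriented logical, whether minus-strand mirroring was applied.
#' @export
setClass("SignalProfile",
  representation(offsets = "integer", values = "numeric", support = "numeric",
                 nSites = "integer", smoothing = "integer", oriented = "logical"))

setValidity("SignalProfile", function(object) {
  msg <- character()
  if (length(object@values) != length(object@offsets))
    msg <- c(msg, "values and offsets lengths differ")
  if (length(object@support) != length(object@offsets))
    msg <- c(msg, "support and offsets lengths differ")
  if (object@nSites <= 0L) msg <- c(msg, "nSites must be positive")
  if (is.unsorted(object@offsets, strictly = TRUE))
    msg <- c(msg, "offsets must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' ProfileShape: modes, asymmetry and minimum of a signal profile
#'
#' Quantifies the qualitative vocabulary used for aggregate mark profiles:
#' number and location of modes (bimodal flanking-nucleosome peaks versus a
#' single displaced maximum), the distance between two modes, the left/right
#' mass asymmetry on a stated flank, and the location of the profile minimum
#' (nucleosome-free-region detection).
#'
#' @slot modeOffsets integer vector of mode positions (bp), sorted.
#' @slot nModes integer.
#' @slot interPeakDistance numeric, difference of the two mode offsets when
#'   `nModes == 2`, otherwise `NA`.
#' @slot asymmetryIndex numeric in `[-1, 1]`: (mass right - mass left) / total
#'   mass, mass taken above the profile baseline.
#' @slot minOffset integer, offset of the profile minimum.
#' @export
setClass("ProfileShape",
  representation(modeOffsets = "integer", nModes = "integer",
                 interPeakDistance = "numeric", asymmetryIndex = "numeric",
                 minOffset = "integer"))

setValidity("ProfileShape", function(object) {
  msg <- character()
  if (object@nModes != length(object@modeOffsets))
    msg <- c(msg, "nModes does not match modeOffsets")
  if (is.unsorted(object@modeOffsets)) msg <- c(msg, "modeOffsets not sorted")
  if (!is.na(object@asymmetryIndex) &&
      (object@asymmetryIndex < -1 || object@asymmetryIndex > 1))
    msg <- c(msg, "asymmetryIndex outside [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' MarkCorrelation: pairwise Spearman coefficients between marks
#'
#' @slot matrix symmetric numeric matrix of Spearman coefficients with unit
#'   diagonal, dimnames = mark names.
#' @slot nObs integer, number of observations (bins or sites) per pair.
#' @slot context single character, e.g. `"genome_bins"`, `"sites"`,
#'   `"sites_proximal"`, `"sites_distal"`, `"sites_activator"`,
#'   `"sites_repressor"`.
#' @export
setClass("MarkCorrelation",
  representation(matrix = "matrix", nObs = "integer", context = "character"))

setValidity("MarkCorrelation", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix not square")
  ok <- is.na(m) | (m >= -1 - 1e-12 & m <= 1 + 1e-12)
  if (!all(ok)) msg <- c(msg, "coefficients outside [-1, 1]")
  if (!isTRUE(all.equal(m, t(m)))) msg <- c(msg, "matrix not symmetric")
  if (length(msg)) msg else TRUE
})
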