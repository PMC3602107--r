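#' Merge tag sets from replicate experiments
#'
#' Concatenates replicate tag sets of the same mark and re-sorts.  Duplicate
#' records are retained: the combined set is the multiset union.
#'
#' @param ... GRanges tag sets, or a single list of them
#' @return a sorted GRanges
#' @export
mergeReplicates <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) &&
      !methods::is(args[[1L]], "GRanges"))
    args <- args[[1L]]
  if (!length(args)) stop("no tag sets supplied")
  .sortTags(do.call(c, args))
}

#' Shift tags to fragment-centre events and index them
#'
#' Each tag is reduced to a single positional event: its 5' end shifted
#' `shift` bp in the 5' to 3' direction (towards the fragment centre).  For a
#' plus-strand tag the event is `start + shift`; for a minus-strand tag it is
#' `end - 1 - shift` (all 0-based).  Events falling outside the chromosome are
#' clamped to its bounds and counted, so the total number of events equals
#' the number of input tags.
#'
#' @param tags GRanges tag set (as from [readTags()])
#' @param chromSizes named integer vector of chromosome lengths; tags on
#'   chromosomes absent from it are rejected
#' @param shift shift in bp (default 100, the standard half fragment length)
#' @param source label stored on the index (`"mark"` or `"control"`)
#' @return a [TagIndex-class]
#' @export
shiftTags <- function(tags, chromSizes, shift = 100, source = "mark") {
  chrom <- as.character(GenomicRanges::seqnames(tags))
  unknown <- setdiff(unique(chrom), names(chromSizes))
  if (length(unknown))
    stop("tags on chromosome(s) absent from chromSizes: ",
         paste(unknown, collapse = ", "))
  plus <- as.character(strand(tags)) == "+"
  # 0-based: BED start = start(gr) - 1; 0-based last base = end(gr) - 1
  ev <- ifelse(plus, (start(tags) - 1L) + shift, (end(tags) - 1L) - shift)
  len <- chromSizes[chrom]
  clamped <- ev < 0L | ev > len - 1L
  ev <- pmin(pmax(ev, 0L), len - 1L)
  positions <- lapply(split(as.integer(ev), chrom), sort)
  # keep empty chromosomes out; validity only requires presence in chromSizes
  methods::new("TagIndex", positions = positions,
               chromSizes = stats::setNames(as.integer(chromSizes),
                                            names(chromSizes)),
               source = source, nClamped = as.integer(sum(clamped)))
}

#' Build a TagIndex directly from event positions
#'
#' Constructor used by the simulator and by callers that already hold
#' per-chromosome 0-based event positions.
#'
#' @param positions named list of integer vectors (0-based positions)
#' @param chromSizes named integer vector of chromosome lengths
#' @param source label (`"mark"` or `"control"`)
#' @return a [TagIndex-class]
#' @export
tagIndex <- function(positions, chromSizes, source = "mark") {
  methods::new("TagIndex",
               positions = lapply(positions, function(p) sort(as.integer(p))),
               chromSizes = stats::setNames(as.integer(chromSizes),
                                            names(chromSizes)),
               source = source, nClamped = 0L)
}

#' Downsample a tag index
#'
#' Uniform sampling without replacement of `n` events, deterministic given
#' `seed`.  Used to compare enrichment at matched sequencing depths.
#'
#' @param index a [TagIndex-class]
#' @param n number of events to keep (`n <= totalCount(index)`)
#' @param seed integer seed
#' @return a [TagIndex-class] with `n` events
#' @export
downsampleTags <- function(index, n, seed) {
  total <- totalCount(index)
  if (n > total) stop("cannot sample ", n, " events from ", total)
  set.seed(seed)
  keep <- sort(sample.int(total, n))
  sizes <- lengths(index@positions)
  chrom <- rep(names(index@positions), sizes)
  all <- unlist(index@positions, use.names = FALSE)
  positions <- split(all[keep], chrom[keep])
  methods::new("TagIndex", positions = lapply(positions, sort),
               chromSizes = index@chromSizes, source = index@source,
               nClamped = index@nClamped)
}

# count of sorted integer positions p with lo <= p <= hi (vectorised over
# lo/hi); positions integer, bounds may be numeric
.countSorted <- function(positions, lo, hi) {
  if (!length(positions)) return(rep(0L, length(lo)))
  findInterval(hi, positions) - findInterval(lo - 1, positions)
}

#' Count tag events in windows centred on positions
#'
#' Counts events in the half-open window `[center - window/2,
#' center + window/2)` (0-based), truncated at chromosome ends.  The
#' effective (truncated) window length is reported alongside the count.
#'
#' @param index a [TagIndex-class]
#' @param chrom character vector of chromosome names (recycled against
#'   `center`)
#' @param center integer vector of 0-based window centres
#' @param window window size in bp (> 0)
#' @return data.frame with columns `count` and `effective_window`
#' @export
countWindow <- function(index, chrom, center, window) {
  if (window <= 0) stop("window must be positive")
  n <- max(length(chrom), length(center))
  chrom <- rep_len(chrom, n); center <- rep_len(center, n)
  unknown <- setdiff(unique(chrom), names(index@chromSizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  half <- window %/% 2
  lo <- center - half
  hi <- lo + window            # exclusive
  len <- as.numeric(index@chromSizes[chrom])
  loT <- pmax(lo, 0); hiT <- pmin(hi, len)
  eff <- pmax(hiT - loT, 0)
  count <- integer(n)
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    count[i] <- .countSorted(tagPositions(index, chr), loT[i], hiT[i] - 1)
  }
  data.frame(count = count, effective_window = eff)
}

#' Count tag events over a non-overlapping genome grid
#'
#' Assigns every event to exactly one bin by integer division of its
#' (shifted) 5'-end position by `binSize`; the last bin of each chromosome is
#' truncated.  The sum over all bins equals the number of events.
#'
#' @param index a [TagIndex-class]
#' @param binSize bin width in bp (default 600)
#' @return a [BinCounts-class]
#' @export
binCounts <- function(index, binSize = 600) {
  if (binSize <= 0) stop("binSize must be positive")
  binSize <- as.integer(binSize)
  counts <- lapply(names(index@chromSizes), function(chr) {
    nb <- as.integer(ceiling(index@chromSizes[[chr]] / binSize))
    p <- tagPositions(index, chr)
    if (!length(p)) return(integer(nb))
    tabulate(p %/% binSize + 1L, nbins = nb)
  })
  names(counts) <- names(index@chromSizes)
  methods::new("BinCounts", binSize = binSize, counts = counts,
               chromSizes = index@chromSizes)
}
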