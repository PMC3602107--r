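# Accumulate per-offset event counts and per-offset site support around a
# set of anchor positions.  orientSign is +1/-1 per site; -1 mirrors the
# site's offsets before accumulation (strand orientation).
.accumulateProfile <- function(index, chrom, pos, flank, orientSign) {
  width <- 2L * flank + 1L
  acc <- numeric(width)
  support <- numeric(width)
  lenv <- index@chromSizes
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    p <- tagPositions(index, chr)
    sp <- pos[i]
    sgn <- orientSign[i]
    len <- lenv[[chr]]
    lo <- pmax(sp - flank, 0)
    hi <- pmin(sp + flank, len - 1)          # inclusive bounds
    first <- findInterval(lo - 1, p) + 1L
    last <- findInterval(hi, p)
    nEv <- pmax(last - first + 1L, 0L)
    if (sum(nEv) > 0) {
      idx <- sequence(nEv, from = first)
      off <- (p[idx] - rep(sp, nEv)) * rep(sgn, nEv)
      acc <- acc + tabulate(off + flank + 1L, nbins = width)
    }
    # support: each site covers offsets [lo-sp, hi-sp] (mirrored when sgn<0)
    oLo <- (lo - sp) * sgn; oHi <- (hi - sp) * sgn
    swap <- sgn < 0
    tmp <- oLo[swap]; oLo[swap] <- oHi[swap]; oHi[swap] <- tmp
    delta <- numeric(width + 1L)
    a <- oLo + flank + 1L; b <- oHi + flank + 2L
    for (k in seq_along(a)) {
      delta[a[k]] <- delta[a[k]] + 1
      delta[b[k]] <- delta[b[k]] - 1
    }
    support <- support + cumsum(delta)[seq_len(width)]
  }
  list(acc = acc, support = support)
}

#' Control-subtracted average signal profile around sites
#'
#' For each site, per-position mark event counts minus per-position control
#' event counts over `[pos - flank, pos + flank]`, averaged across sites.
#' Sites truncated by chromosome ends contribute only their defined
#' positions; the per-offset divisor tracks the number of contributing
#' sites.  Negative net values are kept (subtraction is not clipped).  When
#' `orientStrand` is supplied, the per-site profile of every `"-"` site is
#' mirrored (offset `o` becomes `-o`) before averaging, so that signal
#' downstream in the gene's reading direction appears at positive offsets.
#'
#' @param mark a [TagIndex-class] of mark events
#' @param sites data.frame with columns `chrom`, `pos`
#' @param control a [TagIndex-class] of control events, or `NULL`
#' @param flank half-width of the profile in bp (default 2000)
#' @param orientStrand optional character vector (`"+"`/`"-"`), one per site
#' @return an unsmoothed [SignalProfile-class]
#' @export
netSignalProfile <- function(mark, sites, control = NULL, flank = 2000,
                             orientStrand = NULL) {
  if (!nrow(sites)) stop("empty site set")
  if (flank <= 0) stop("flank must be positive")
  flank <- as.integer(flank)
  unknown <- setdiff(unique(sites$chrom), names(mark@chromSizes))
  if (length(unknown))
    stop("sites on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  sgn <- if (is.null(orientStrand)) rep(1L, nrow(sites))
         else ifelse(orientStrand == "-", -1L, 1L)
  m <- .accumulateProfile(mark, sites$chrom, sites$pos, flank, sgn)
  values <- m$acc
  if (!is.null(control)) {
    cc <- .accumulateProfile(control, sites$chrom, sites$pos, flank, sgn)
    values <- values - cc$acc
  }
  div <- ifelse(m$support > 0, m$support, 1)
  methods::new("SignalProfile", offsets = seq(-flank, flank),
               values = values / div, support = m$support,
               nSites = nrow(sites), smoothing = 0L,
               oriented = !is.null(orientStrand))
}

#' Assign sites to their nearest gene TSS
#'
#' Each site is assigned to the transcript whose TSS minimises
#' `|pos - tss|`; ties are broken towards the smaller TSS coordinate.  The
#' signed distance is positive when the site lies downstream of the TSS in
#' the gene's reading direction.
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos`
#' @param transcripts data.frame as from [readAnnotation()]
#' @return data.frame with columns `site_id`, `transcript_id`,
#'   `gene_strand`, `tss`, `distance` (absolute bp), `signed_distance`
#' @export
orientSitesByNearestGene <- function(sites, transcripts) {
  if (!nrow(transcripts)) stop("no transcripts supplied")
  out <- data.frame(site_id = sites$site_id,
                    transcript_id = NA_character_,
                    gene_strand = NA_character_, tss = NA_integer_,
                    distance = NA_real_, signed_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (chr in unique(sites$chrom)) {
    si <- which(sites$chrom == chr)
    tx <- transcripts[transcripts$chrom == chr, , drop = FALSE]
    if (!nrow(tx)) {
      warning("no transcripts on ", chr, "; sites there left unassigned")
      next
    }
    o <- order(tx$tss, tx$transcript_id)
    tx <- tx[o, , drop = FALSE]
    tss <- tx$tss
    pos <- sites$pos[si]
    k <- findInterval(pos, tss)               # index of last tss <= pos
    loI <- pmax(k, 1L); hiI <- pmin(k + 1L, length(tss))
    dLo <- abs(pos - tss[loI]); dHi <- abs(pos - tss[hiI])
    # tie (dLo == dHi) -> smaller tss coordinate, i.e. loI
    pick <- ifelse(k == 0L, hiI, ifelse(dHi < dLo, hiI, loI))
    out$transcript_id[si] <- tx$transcript_id[pick]
    out$gene_strand[si] <- tx$strand[pick]
    out$tss[si] <- tss[pick]
    d <- pos - tss[pick]
    out$distance[si] <- abs(d)
    out$signed_distance[si] <- ifelse(tx$strand[pick] == "+", d, -d)
  }
  out
}

#' Strand-oriented average profile around sites
#'
#' Convenience wrapper: assigns every site to its nearest gene with
#' [orientSitesByNearestGene()], mirrors the per-site profiles of sites
#' whose gene is on the minus strand, and averages.  Averaging without this
#' reversal artificially symmetrises any signal that is one-sided with
#' respect to transcription.
#'
#' @inheritParams netSignalProfile
#' @param transcripts data.frame as from [readAnnotation()]
#' @return an unsmoothed, oriented [SignalProfile-class]
#' @export
orientByNearestGene <- function(mark, sites, transcripts, control = NULL,
                                flank = 2000) {
  asg <- orientSitesByNearestGene(sites, transcripts)
  if (anyNA(asg$gene_strand)) stop("some sites could not be assigned to a gene")
  netSignalProfile(mark, sites, control, flank,
                   orientStrand = asg$gene_strand)
}

#' Average profile around transcription start sites
#'
#' As [netSignalProfile()] with TSSs as anchors, oriented by each
#' transcript's own strand (minus-strand profiles mirrored), so positive
#' offsets point into the gene body.
#'
#' @inheritParams netSignalProfile
#' @param transcripts data.frame as from [readAnnotation()]
#' @return an unsmoothed, oriented [SignalProfile-class]
#' @export
tssProfile <- function(mark, transcripts, control = NULL, flank = 2000) {
  if (!nrow(transcripts)) stop("no transcripts supplied")
  anchors <- data.frame(site_id = transcripts$transcript_id,
                        chrom = transcripts$chrom, pos = transcripts$tss,
                        stringsAsFactors = FALSE)
  netSignalProfile(mark, anchors, control, flank,
                   orientStrand = transcripts$strand)
}

#' Smooth a signal profile with a centred moving average
#'
#' Each value is replaced by the mean over a window of `window` positions
#' centred on it (for even windows, one position more to the right than to
#' the left); at the profile edges the window is truncated and the mean
#' taken over the available positions.
#'
#' @param profile a [SignalProfile-class]
#' @param window smoothing window in bp/positions (default 200)
#' @return a [SignalProfile-class] with `smoothing` recorded
#' @export
smoothProfile <- function(profile, window = 200) {
  n <- length(profile@values)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("smoothing window larger than profile span")
  window <- as.integer(window)
  h1 <- (window - 1L) %/% 2L
  h2 <- window - 1L - h1
  i <- seq_len(n)
  lo <- pmax(i - h1, 1L); hi <- pmin(i + h2, n)
  cs <- c(0, cumsum(profile@values))
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  methods::new("SignalProfile", offsets = profile@offsets, values = sm,
               support = profile@support, nSites = profile@nSites,
               smoothing = window, oriented = profile@oriented)
}

#' Characterise the shape of a signal profile
#'
#' A mode is a position whose value is strictly greater than every other
#' value within `modeRadius` bp and exceeds
#' `baseline + minProminence * (max - baseline)`, with the baseline taken as
#' the median profile value.  Also reported: the inter-peak distance when
#' exactly two modes are found, the offset of the profile minimum (ties
#' resolved towards the centre; used for nucleosome-free-region location),
#' and the asymmetry index `(mass right - mass left) / (mass right + mass
#' left)` where mass is the profile above baseline within `flank` bp of the
#' centre.
#'
#' @param profile a (smoothed) [SignalProfile-class]
#' @param minProminence fraction of the baseline-to-max range a mode must
#'   exceed (default 0.1)
#' @param modeRadius local-maximum radius in bp (default 100, about half a
#'   nucleosome repeat)
#' @param flank half-width over which the asymmetry mass is computed
#'   (default: the whole profile)
#' @return a [ProfileShape-class]
#' @export
detectShape <- function(profile, minProminence = 0.1, modeRadius = 100,
                        flank = NULL) {
  v <- profile@values
  off <- profile@offsets
  n <- length(v)
  if (is.null(flank)) flank <- max(abs(off))
  baseline <- median(v)
  vmax <- max(v)
  thr <- baseline + minProminence * (vmax - baseline)
  modes <- integer(0)
  if (vmax > baseline) {
    # windowed maximum; a mode position attains it.  Averaged count data can
    # tie exactly, so tied maxima within one radius are treated as a single
    # plateau and reported at the plateau midpoint.
    loIdx <- findInterval(off - modeRadius - 0.5, off) + 1L
    hiIdx <- findInterval(off + modeRadius + 0.5, off)
    wmax <- vapply(seq_len(n), function(i) max(v[loIdx[i]:hiIdx[i]]),
                   numeric(1))
    cand <- which(v > thr & v >= wmax)
    if (length(cand)) {
      grp <- cumsum(c(1L, diff(cand) > modeRadius))
      modes <- vapply(split(cand, grp), function(ix)
        off[ix[ceiling(length(ix) / 2)]], integer(1))
    }
  }
  modes <- sort(unname(modes))
  mass <- pmax(v - baseline, 0)
  right <- sum(mass[off > 0 & off <= flank])
  left <- sum(mass[off < 0 & off >= -flank])
  asym <- if (right + left > 0) (right - left) / (right + left) else 0
  mins <- which(v == min(v))
  minOff <- off[mins[which.min(abs(off[mins]))]]
  methods::new("ProfileShape", modeOffsets = as.integer(modes),
               nModes = length(modes),
               interPeakDistance = if (length(modes) == 2L)
                 as.numeric(diff(modes)) else NA_real_,
               asymmetryIndex = asym, minOffset = as.integer(minOff))
}
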