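#' Genome-wide background rate for a scoring window
#'
#' Expected number of tags falling in a window of the given size if the
#' library were scattered uniformly over the genome:
#' `totalTags * window / genomeLength`.
#'
#' @param totalTags total number of tag events in the library
#' @param genomeLength genome length in bp (sum of chromosome sizes)
#' @param window scoring window in bp (> 0)
#' @return expected tag count (numeric scalar)
#' @export
lambdaBg <- function(totalTags, genomeLength, window) {
  if (window <= 0) stop("window must be positive")
  if (genomeLength <= 0) stop("genomeLength must be positive")
  totalTags * window / genomeLength
}

#' Dynamic local Poisson expectation at sites
#'
#' For each site, control tags are counted in 1-kb, 5-kb and 10-kb regions
#' centred on it (truncated at chromosome ends) and rescaled to the scoring
#' window: `lambda_L = count_L * window / effective_L`.  The local rate is
#' the maximum of these and of the genome-wide background rate computed from
#' the control's own total count, so the background can only be raised, never
#' lowered, by local fluctuations:
#' `lambda_local = max(lambda_bg, lambda_1k, lambda_5k, lambda_10k)`.
#'
#' @param control a [TagIndex-class] of control (input) tag events
#' @param chrom,pos site chromosome(s) and 0-based position(s)
#' @param window scoring window in bp
#' @return data.frame with columns `lambda_bg`, `lambda_1k`, `lambda_5k`,
#'   `lambda_10k`, `lambda_local`
#' @export
lambdaLocal <- function(control, chrom, pos, window) {
  lbg <- lambdaBg(totalCount(control), genomeLength(chromSizes(control)),
                  window)
  comp <- lapply(c(1000, 5000, 10000), function(L) {
    cw <- countWindow(control, chrom, pos, L)
    ifelse(cw$effective_window > 0,
           cw$count * window / cw$effective_window, 0)
  })
  out <- data.frame(lambda_bg = lbg, lambda_1k = comp[[1L]],
                    lambda_5k = comp[[2L]], lambda_10k = comp[[3L]])
  out$lambda_local <- pmax(out$lambda_bg, out$lambda_1k, out$lambda_5k,
                           out$lambda_10k)
  out
}

#' Poisson enrichment threshold
#'
#' The smallest integer `t >= 0` whose upper-tail probability under
#' `Poisson(lambda)` is below `alpha`: `P(X > t) < alpha`.  Computed from the
#' upper-tail distribution function; monotone non-decreasing in `lambda`.
#'
#' @param lambda Poisson rate(s), `>= 0` (vectorised)
#' @param alpha tail probability (default `1e-4`)
#' @return integer vector of thresholds
#' @export
poissonThreshold <- function(lambda, alpha = 1e-4) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  # smallest t with P(X <= t) >= 1 - alpha, then push up while the strict
  # inequality P(X > t) < alpha is not yet met (qpois guarantees <= alpha)
  t <- qpois(alpha, lambda, lower.tail = FALSE)
  repeat {
    bad <- ppois(t, lambda, lower.tail = FALSE) >= alpha
    if (!any(bad)) break
    t[bad] <- t[bad] + 1L
  }
  as.integer(t)
}

#' Call per-site enrichment of a mark
#'
#' For each site, the mark tag count `X` in the half-open window centred on
#' the site is compared with the threshold `t` derived from the dynamic local
#' Poisson rate; the site is enriched iff `X > t` (strict).  When no control
#' is supplied the local rate falls back to the genome-wide background rate
#' of the mark itself (a message is emitted).
#'
#' @param mark a [TagIndex-class] of mark tag events
#' @param sites data.frame of sites (columns `site_id`, `chrom`, `pos`, and
#'   optionally `tf`)
#' @param control a [TagIndex-class] of control events, or `NULL`
#' @param window scoring window in bp (default 600)
#' @param alpha Poisson tail probability (default `1e-4`)
#' @return data.frame with one row per site: `site_id`, `tf` (if present),
#'   `window`, `observed`, `lambda_local`, `threshold`, `enriched`
#' @export
callEnrichment <- function(mark, sites, control = NULL, window = 600,
                           alpha = 1e-4) {
  if (!nrow(sites)) stop("empty site set")
  if (!is.null(control) &&
      !identical(chromSizes(mark), chromSizes(control)))
    stop("mark and control indexes use different chromosome sizes")
  x <- countWindow(mark, sites$chrom, sites$pos, window)$count
  if (is.null(control)) {
    message("no control supplied; using the mark's genome-wide background rate")
    lam <- rep(lambdaBg(totalCount(mark), genomeLength(chromSizes(mark)),
                        window), nrow(sites))
  } else {
    lam <- lambdaLocal(control, sites$chrom, sites$pos, window)$lambda_local
  }
  t <- poissonThreshold(lam, alpha)
  out <- data.frame(site_id = sites$site_id, window = window, observed = x,
                    lambda_local = lam, threshold = t, enriched = x > t,
                    stringsAsFactors = FALSE)
  if ("tf" %in% names(sites)) out$tf <- sites$tf
  out
}

#' Enrichment-proportion curve over window sizes
#'
#' Re-calls enrichment at each window of a grid and reports the proportion of
#' sites enriched, optionally split by a site grouping (e.g. proximal/distal
#' or activator/repressor).  Short-range marks plateau once the window covers
#' the flanking-nucleosome span; long-range marks keep rising.
#'
#' @param mark,sites,control,alpha as in [callEnrichment()]
#' @param windows integer vector of window sizes (default
#'   `seq(200, 4000, by = 200)`)
#' @param groups optional factor/character vector, one label per site; when
#'   supplied proportions are reported per group as well as for `"all"`
#' @return data.frame with columns `window`, `group`, `n_sites`,
#'   `n_enriched`, `proportion`
#' @export
enrichmentCurve <- function(mark, sites, control = NULL,
                            windows = seq(200, 4000, by = 200),
                            alpha = 1e-4, groups = NULL) {
  if (!nrow(sites)) stop("empty site set")
  grp <- if (is.null(groups)) rep("all", nrow(sites))
         else as.character(groups)
  do.call(rbind, lapply(windows, function(w) {
    calls <- callEnrichment(mark, sites, control, window = w, alpha = alpha)
    labs <- unique(c("all", grp))
    do.call(rbind, lapply(labs, function(g) {
      sel <- if (g == "all") rep(TRUE, nrow(calls)) else grp == g
      data.frame(window = w, group = g, n_sites = sum(sel),
                 n_enriched = sum(calls$enriched[sel]),
                 proportion = mean(calls$enriched[sel]))
    }))
  }))
}

#' One-sided binomial test of site enrichment against a background rate
#'
#' Exact upper-tail binomial p-value for observing at least `kEnriched`
#' enriched sites out of `nSites` when each is enriched with probability
#' `p0` (the genome-background proportion, e.g. estimated from decoy sites).
#'
#' @param kEnriched number of enriched sites
#' @param nSites number of sites
#' @param p0 background enrichment proportion, in (0, 1)
#' @return p-value, `P(K >= kEnriched)`
#' @export
binomialSiteTest <- function(kEnriched, nSites, p0) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (kEnriched < 0 || kEnriched > nSites) stop("need 0 <= kEnriched <= nSites")
  pbinom(kEnriched - 1, nSites, p0, lower.tail = FALSE)
}

#' Estimate the genome-background enrichment proportion from decoy sites
#'
#' Places `nDecoys` positions uniformly at random over the genome (seeded),
#' applies the same enrichment rule as [callEnrichment()], and returns the
#' fraction called enriched.  This serves as `p0` for [binomialSiteTest()].
#'
#' @param mark,control,window,alpha as in [callEnrichment()]
#' @param nDecoys number of decoy sites (default 10000)
#' @param seed integer seed for decoy placement
#' @return list with `p0`, `n_decoys`, `n_enriched`, `seed`
#' @export
estimateBackgroundProportion <- function(mark, control = NULL, window = 600,
                                         alpha = 1e-4, nDecoys = 10000,
                                         seed = 1) {
  cs <- chromSizes(mark)
  set.seed(seed)
  chrom <- sample(names(cs), nDecoys, replace = TRUE,
                  prob = as.numeric(cs) / genomeLength(cs))
  pos <- as.integer(floor(runif(nDecoys) * cs[chrom]))
  decoys <- data.frame(site_id = sprintf("decoy_%06d", seq_len(nDecoys)),
                       chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  calls <- callEnrichment(mark, decoys, control, window, alpha)
  list(p0 = mean(calls$enriched), n_decoys = nDecoys,
       n_enriched = sum(calls$enriched), seed = seed)
}

#' Paired Wilcoxon signed-rank test between two proportion vectors
#'
#' Compares paired per-unit values (by default per-TF enrichment
#' proportions), e.g. proximal versus distal enrichment.  Zero differences
#' are dropped; `|differences|` receive average ranks.  For `n <= 25`
#' non-zero pairs the exact null distribution of the positive-rank sum is
#' computed by its generating function (valid under ties, where the
#' permutation-exact `wilcox.test` is unavailable); beyond that a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param a,b numeric vectors of equal length, paired by unit
#' @param alternative `"greater"` (a > b), `"less"`, or `"two.sided"`
#' @return p-value
#' @export
wilcoxonPaired <- function(a, b, alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # distribution of 2*W over the 2^n sign assignments (2x keeps average
    # ranks on an integer grid)
    w2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(w2)))
    for (x in w2)
      counts <- counts + c(numeric(x), counts[seq_len(length(counts) - x)])
    i <- as.integer(round(2 * W)) + 1L
    pg <- sum(counts[i:length(counts)]) / 2^n
    pl <- sum(counts[seq_len(i)]) / 2^n
  } else {
    mu <- sum(r) / 2
    sig <- sqrt(sum(r^2) / 4)
    pg <- stats::pnorm((W - mu - 0.5) / sig, lower.tail = FALSE)
    pl <- stats::pnorm((W - mu + 0.5) / sig)
  }
  switch(alternative, greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}
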