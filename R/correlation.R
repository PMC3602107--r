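#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks).  When either vector has zero variance the coefficient is
#' undefined and returned as `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length `>= 3`
#' @return Spearman coefficient, or `NA`
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; Spearman coefficient undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

.spearmanMatrix <- function(mat, context) {
  marks <- colnames(mat)
  k <- length(marks)
  m <- diag(1, k)
  dimnames(m) <- list(marks, marks)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    m[i, j] <- m[j, i] <- spearmanCor(mat[, i], mat[, j])
  }
  methods::new("MarkCorrelation", matrix = m, nObs = nrow(mat),
               context = context)
}

#' Pairwise mark correlation over genome bins
#'
#' Spearman correlation of per-bin tag counts between every pair of marks,
#' over the non-overlapping genome grid.  Zero-count bins are included by
#' default (the grid covers the whole genome, not only its covered part);
#' `nonzeroOnly = TRUE` restricts to bins where at least one mark has a tag,
#' which materially changes coefficients on sparse genomes.
#'
#' @param binList named list of [BinCounts-class], one per mark, on an
#'   identical grid
#' @param nonzeroOnly drop bins that are zero in every mark (default FALSE)
#' @return a [MarkCorrelation-class] with context `"genome_bins"`
#' @export
genomeCorrelation <- function(binList, nonzeroOnly = FALSE) {
  if (length(binList) < 2) stop("need at least two marks")
  if (is.null(names(binList)) || any(!nzchar(names(binList))))
    stop("binList must be named by mark")
  ref <- binList[[1L]]
  for (b in binList[-1L]) {
    if (b@binSize != ref@binSize ||
        !identical(b@chromSizes, ref@chromSizes))
      stop("bin grids differ between marks")
  }
  mat <- vapply(binList, function(b)
    unlist(b@counts[names(ref@counts)], use.names = FALSE),
    numeric(sum(lengths(ref@counts))))
  if (nonzeroOnly) mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  .spearmanMatrix(mat, "genome_bins")
}

#' Pairwise mark correlation over per-site window counts
#'
#' For each mark, tags are counted in a window centred on every site; the
#' Spearman correlation across sites is computed for every pair of marks.
#' Counts are raw mark counts by default, mirroring the enrichment
#' statistic; `subtractControl = TRUE` subtracts the control count in the
#' same window.
#'
#' @param markList named list of [TagIndex-class], one per mark
#' @param sites data.frame with columns `chrom`, `pos` (same site set for
#'   all marks; at least 3 sites)
#' @param window window size in bp (default 600)
#' @param control optional [TagIndex-class] used when `subtractControl`
#' @param subtractControl subtract control window counts (default FALSE)
#' @param context label stored on the result (default `"sites"`)
#' @return a [MarkCorrelation-class]
#' @export
siteCorrelation <- function(markList, sites, window = 600, control = NULL,
                            subtractControl = FALSE, context = "sites") {
  if (length(markList) < 2) stop("need at least two marks")
  if (is.null(names(markList)) || any(!nzchar(names(markList))))
    stop("markList must be named by mark")
  if (nrow(sites) < 3) stop("need at least 3 sites")
  ctrl <- if (subtractControl) {
    if (is.null(control)) stop("subtractControl = TRUE requires a control")
    countWindow(control, sites$chrom, sites$pos, window)$count
  } else 0
  mat <- vapply(markList, function(ix)
    countWindow(ix, sites$chrom, sites$pos, window)$count - ctrl,
    numeric(nrow(sites)))
  .spearmanMatrix(mat, context)
}
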