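# small in-code fixtures shared across test files

writeTempLines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# BED line from 0-based coordinates
bedLine <- function(chrom, start, end, score, strand, name = "t") {
  sprintf("%s\t%d\t%d\t%s\t%s\t%s", chrom, start, end, name,
          format(score), strand)
}

# TagIndex straight from per-chromosome event positions
makeIndex <- function(events, sizes, source = "mark") {
  tagIndex(events, sizes, source = source)
}

# deterministic toy transcript table
makeTranscripts <- function(tss, strand, chrom = "chr1",
                            expression = NULL) {
  n <- length(tss)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             transcript_id = sprintf("t%02d", seq_len(n)),
             chrom = rep_len(chrom, n), strand = rep_len(strand, n),
             tss = as.integer(tss), exon_bp = rep(1000L, n),
             expression = if (is.null(expression)) rep(1, n)
                          else expression,
             stringsAsFactors = FALSE)
}

makeSites <- function(pos, chrom = "chr1", tf = "TF1") {
  n <- length(pos)
  data.frame(site_id = sprintf("s%03d", seq_len(n)),
             chrom = rep_len(chrom, n), pos = as.integer(pos),
             tf = rep_len(tf, n), stringsAsFactors = FALSE)
}

# independent oracle: smallest t with P(X > t) < alpha by direct pmf summation
bruteThreshold <- function(lambda, alpha) {
  if (lambda == 0) return(0L)
  t <- 0L
  cum <- dpois(0, lambda)
  repeat {
    if (1 - cum < alpha) return(t)
    t <- t + 1L
    cum <- cum + dpois(t, lambda)
  }
}

# independent oracle: count events in [lo, hi) by linear scan
bruteCount <- function(events, lo, hi) sum(events >= lo & events < hi)

# independent oracle: Spearman as rank-then-Pearson
bruteSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent oracle: exact one-sided signed-rank p by enumerating sign flips
bruteSignedRank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  total <- 0
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m)[1:n])
    if (sum(r[signs == 1]) >= obs) total <- total + 1
  }
  total / 2^n
}
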