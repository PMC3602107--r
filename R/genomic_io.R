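#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols `mcols<-`
NULL

.readLinesNoComment <- function(path) {
  if (!is.character(path) || !file.exists(path))
    stop("cannot open file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.splitFields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.parseStop <- function(lineno, what) {
  stop(sprintf("parse error at line %d: %s", lineno, what), call. = FALSE)
}

#' Read a chromosome-sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.  The genome
#' length used for the genome-wide background rate is the sum of the entries.
#'
#' @param path file path
#' @return named integer vector of chromosome lengths
#' @export
readChromSizes <- function(path) {
  lc <- .readLinesNoComment(path)
  f <- .splitFields(lc$lines)
  for (i in seq_along(f)) {
    if (length(f[[i]]) < 2L) .parseStop(lc$lineno[i], "expected 2 columns")
  }
  nm <- vapply(f, `[[`, character(1), 1L)
  len <- suppressWarnings(as.integer(vapply(f, `[[`, character(1), 2L)))
  bad <- which(is.na(len) | len <= 0L)
  if (length(bad)) .parseStop(lc$lineno[bad[1L]], "invalid chromosome length")
  if (anyDuplicated(nm)) stop("duplicated chromosome name in ", path)
  stats::setNames(len, nm)
}

#' Total genome length of a chromosome-sizes vector
#' @param sizes named integer vector as returned by [readChromSizes()]
#' @return numeric scalar, sum of chromosome lengths
#' @export
genomeLength <- function(sizes) sum(as.numeric(sizes))

#' Read sequenced tags from a BED6 file
#'
#' Each record is one sequenced-fragment tag: chrom, start (0-based), end
#' (exclusive), name, score, strand.  The score column carries the mapping
#' quality; records with `score < minScore` are filtered out (a score exactly
#' equal to `minScore` is kept).  Records are returned sorted by
#' (chrom, start).
#'
#' @param path BED file path (>= 6 columns, tab-separated, `#` comments)
#' @param minScore minimum quality score retained (default 10)
#' @return a [GenomicRanges::GRanges] with a `score` metadata column;
#'   coordinates 1-based closed (BED start + 1)
#' @export
readTags <- function(path, minScore = 10) {
  lc <- .readLinesNoComment(path)
  if (!length(lc$lines))
    return(GRanges(score = integer(0)))
  f <- .splitFields(lc$lines)
  short <- which(lengths(f) < 6L)
  if (length(short)) .parseStop(lc$lineno[short[1L]], "expected >= 6 columns")
  m <- vapply(f, function(x) x[1:6], character(6))
  chrom <- m[1L, ]
  start0 <- suppressWarnings(as.integer(m[2L, ]))
  end0 <- suppressWarnings(as.integer(m[3L, ]))
  score <- suppressWarnings(as.numeric(m[5L, ]))
  strand <- m[6L, ]
  bad <- which(is.na(start0) | is.na(end0) | is.na(score))
  if (length(bad)) .parseStop(lc$lineno[bad[1L]], "non-numeric coordinate or score")
  bad <- which(start0 < 0L | start0 >= end0)
  if (length(bad))
    .parseStop(lc$lineno[bad[1L]], "invalid interval (requires 0 <= start < end)")
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) .parseStop(lc$lineno[bad[1L]], "strand must be + or -")
  keep <- score >= minScore
  gr <- GRanges(chrom[keep], IRanges(start0[keep] + 1L, end0[keep]),
                strand = strand[keep], score = as.integer(score[keep]))
  .sortTags(gr)
}

.sortTags <- function(gr) {
  o <- order(as.character(GenomicRanges::seqnames(gr)), start(gr), end(gr),
             as.character(strand(gr)))
  gr[o]
}

#' Write tags to a BED6 file
#'
#' Inverse of [readTags()]: 1-based GRanges coordinates become 0-based
#' half-open BED coordinates.  The name column is written as `"."`.
#'
#' @param tags GRanges with `score` metadata column
#' @param path output path
#' @return invisibly, the path
#' @export
writeTags <- function(tags, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(tags)),
                   start = start(tags) - 1L, end = end(tags), name = ".",
                   score = mcols(tags)$score,
                   strand = as.character(strand(tags)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TF binding sites
#'
#' Two source conventions are supported.  `mode = "point"` reads a
#' tab-separated file with a header line `chrom  pos  tf` of point sites
#' (0-based positions), as produced by footprint-based site maps.
#' `mode = "peak"` reads BED intervals with the TF name in column 4; the
#' centre of each peak, `floor((start + end) / 2)` in 0-based coordinates, is
#' taken as the binding site.
#'
#' @param path file path
#' @param mode `"point"` or `"peak"`
#' @return data.frame with columns `site_id`, `chrom`, `pos` (0-based),
#'   `tf`, `source`
#' @export
readSites <- function(path, mode = c("point", "peak")) {
  mode <- match.arg(mode)
  lc <- .readLinesNoComment(path)
  f <- .splitFields(lc$lines)
  if (mode == "point") {
    if (!length(f)) stop("empty site file: ", path)
    hdr <- f[[1L]]
    if (!identical(tolower(hdr[1:3]), c("chrom", "pos", "tf")))
      .parseStop(lc$lineno[1L], "expected header 'chrom\tpos\ttf'")
    f <- f[-1L]; lineno <- lc$lineno[-1L]
    short <- which(lengths(f) < 3L)
    if (length(short)) .parseStop(lineno[short[1L]], "expected 3 columns")
    chrom <- vapply(f, `[[`, character(1), 1L)
    pos <- suppressWarnings(as.integer(vapply(f, `[[`, character(1), 2L)))
    tf <- vapply(f, `[[`, character(1), 3L)
    bad <- which(is.na(pos) | pos < 0L)
    if (length(bad)) .parseStop(lineno[bad[1L]], "invalid (negative?) position")
    src <- "point"
  } else {
    short <- which(lengths(f) < 4L)
    if (length(short)) .parseStop(lc$lineno[short[1L]], "expected >= 4 columns")
    chrom <- vapply(f, `[[`, character(1), 1L)
    s <- suppressWarnings(as.integer(vapply(f, `[[`, character(1), 2L)))
    e <- suppressWarnings(as.integer(vapply(f, `[[`, character(1), 3L)))
    tf <- vapply(f, `[[`, character(1), 4L)
    bad <- which(is.na(s) | is.na(e) | s < 0L | s >= e)
    if (length(bad)) .parseStop(lc$lineno[bad[1L]], "invalid peak interval")
    pos <- (s + e) %/% 2L
    src <- "peak_center"
  }
  data.frame(site_id = sprintf("site_%06d", seq_along(chrom)),
             chrom = chrom, pos = pos, tf = tf, source = src,
             stringsAsFactors = FALSE)
}

#' Read a transcript annotation table
#'
#' Tab-separated, header line, refFlat-like columns: `gene_id`,
#' `transcript_id`, `chrom`, `strand`, `txStart` (0-based), `txEnd`
#' (exclusive), `exon_bp` (summed exon length), `coding`
#' (`coding`/`noncoding`), and optionally `expression` (RPKM).
#' Non-protein-coding records are dropped.  The TSS is `txStart` for
#' plus-strand transcripts and `txEnd - 1` (0-based last base) for
#' minus-strand transcripts.
#'
#' @param path file path
#' @return data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `tss` (0-based), `exon_bp`, `expression` (NA when absent)
#' @export
readAnnotation <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "chrom", "strand", "txStart",
            "txEnd", "exon_bp", "coding")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!tab$strand %in% c("+", "-")))
    stop("record error: annotation strand must be + or -")
  if (any(tab$exon_bp <= 0)) stop("record error: exon_bp must be positive")
  tab <- tab[tab$coding == "coding", , drop = FALSE]
  tss <- ifelse(tab$strand == "+", tab$txStart, tab$txEnd - 1L)
  data.frame(gene_id = tab$gene_id, transcript_id = tab$transcript_id,
             chrom = tab$chrom, strand = tab$strand, tss = as.integer(tss),
             exon_bp = as.integer(tab$exon_bp),
             expression = if ("expression" %in% names(tab))
               as.numeric(tab$expression) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Read a TF role table
#'
#' Tab-separated with header `tf  role`, role one of `activator`,
#' `repressor`, `both`.  Each TF may appear at most once.
#'
#' @param path file path
#' @return data.frame with columns `tf`, `role`
#' @export
readRoles <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("tf", "role") %in% names(tab)))
    stop("role table needs columns 'tf' and 'role'")
  if (anyDuplicated(tab$tf))
    stop("record error: TF appears more than once in role table")
  if (any(!tab$role %in% c("activator", "repressor", "both")))
    stop("record error: role must be activator, repressor or both")
  tab[, c("tf", "role")]
}

#' Write bin counts as a bedGraph-like TSV
#'
#' Columns: chrom, start (0-based), end (exclusive, truncated at the
#' chromosome end), count.
#'
#' @param bins a [BinCounts-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeBinCounts <- function(bins, path) {
  out <- do.call(rbind, lapply(names(bins@counts), function(chr) {
    n <- length(bins@counts[[chr]])
    s <- (seq_len(n) - 1L) * bins@binSize
    data.frame(chrom = chr, start = s,
               end = pmin(s + bins@binSize, bins@chromSizes[[chr]]),
               count = bins@counts[[chr]])
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a signal profile as TSV
#'
#' Columns (with header): offset, value, n (per-offset contributing sites).
#'
#' @param profile a [SignalProfile-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeProfile <- function(profile, path) {
  utils::write.table(
    data.frame(offset = profile@offsets, value = profile@values,
               n = profile@support),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
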