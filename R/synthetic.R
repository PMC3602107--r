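#' Per-mark specification for the synthetic generator
#'
#' Describes one simulated ChIP-seq mark: a uniform Poisson background plus,
#' at enriched sites, extra tags drawn around each planted peak offset with
#' normal positional spread.  `fold` is the ratio of the peak-centre tag
#' density to the background density; the expected number of extra tags per
#' site and peak is `(fold - 1) * backgroundRate * sqrt(2 * pi) * peakSd`.
#' `oriented` marks flip their peak offsets at sites assigned to
#' minus-strand genes (one-sided signal tied to transcription direction).
#' `nfr = TRUE` makes an occupancy-like track: background tags within
#' `nfrWidth / 2` of any site are suppressed (nucleosome-free region).
#' `atSites = FALSE` plants the peaks at a private random position set
#' instead of the shared binding sites (for correlation contrasts).
#'
#' @param backgroundRate background tag density, tags per bp (default 0.01)
#' @param peakOffsets signed peak centre offsets in bp (default
#'   `c(-200, 200)`, flanking-nucleosome bimodal)
#' @param peakSd normal positional spread of planted tags in bp (default 60)
#' @param fold peak/background density ratio, `>= 1` (default 8)
#' @param oriented flip offsets at minus-strand-gene sites (default FALSE)
#' @param enrichedFraction fraction of sites that receive planted tags
#'   (default 0.7)
#' @param atSites plant at the shared binding sites (default TRUE)
#' @param nfr suppress background around sites (default FALSE)
#' @return a list of class `markSpec`
#' @export
markSpec <- function(backgroundRate = 0.01, peakOffsets = c(-200, 200),
                     peakSd = 60, fold = 8, oriented = FALSE,
                     enrichedFraction = 0.7, atSites = TRUE, nfr = FALSE) {
  if (backgroundRate < 0) stop("backgroundRate must be >= 0")
  if (fold < 1) stop("fold must be >= 1")
  if (peakSd <= 0) stop("peakSd must be positive")
  if (enrichedFraction < 0 || enrichedFraction > 1)
    stop("enrichedFraction must be in [0, 1]")
  structure(list(backgroundRate = backgroundRate, peakOffsets = peakOffsets,
                 peakSd = peakSd, fold = fold, oriented = oriented,
                 enrichedFraction = enrichedFraction, atSites = atSites,
                 nfr = nfr), class = "markSpec")
}

#' Configuration of a synthetic chromatin dataset
#'
#' Defines a small genome with genes, TF binding sites (a planted mixture of
#' TSS-proximal and TSS-distal placements), one or more simulated marks, and
#' a matched structureless control, all driven by a single seed.
#'
#' @param nChroms number of chromosomes (default 2)
#' @param chromLength chromosome length in bp (default 1e6)
#' @param nGenes total number of genes (default 100)
#' @param minusStrandFraction fraction of genes on the minus strand
#'   (default 0.5)
#' @param nTfs number of TFs (default 4; roles alternate
#'   activator/repressor)
#' @param sitesPerTf binding sites per TF (default 250)
#' @param proximalFraction fraction of sites planted within 1 kb of a TSS
#'   (default 0.3, matching the reported share of promoter-proximal
#'   footprint sites); the remainder is planted beyond 10 kb of every TSS
#' @param marks named list of [markSpec()] objects (default one bimodal
#'   mark)
#' @param controlRate control tag density, tags per bp (default 0.01)
#' @param nfrWidth width of the suppressed region for occupancy-like marks,
#'   bp (default 200)
#' @param tagLength emitted tag length in bp (default 36)
#' @param shift the 5'-to-3' shift the analysis will apply (default 100);
#'   tags are emitted so that [shiftTags()] recovers planted event
#'   positions exactly
#' @param seed integer seed driving every draw
#' @return a list of class `syntheticConfig`
#' @export
syntheticConfig <- function(nChroms = 2, chromLength = 1e6, nGenes = 100,
                            minusStrandFraction = 0.5, nTfs = 4,
                            sitesPerTf = 250, proximalFraction = 0.3,
                            marks = list(mark = markSpec()),
                            controlRate = 0.01, nfrWidth = 200,
                            tagLength = 36, shift = 100, seed = 1) {
  if (controlRate < 0) stop("controlRate must be >= 0")
  if (is.null(names(marks)) || any(!nzchar(names(marks))))
    stop("marks must be a named list")
  if (proximalFraction < 0 || proximalFraction > 1)
    stop("proximalFraction must be in [0, 1]")
  if (chromLength < 30000)
    stop("chromLength too small to place sites away from chromosome ends")
  cfg <- list(nChroms = nChroms, chromLength = chromLength, nGenes = nGenes,
              minusStrandFraction = minusStrandFraction, nTfs = nTfs,
              sitesPerTf = sitesPerTf, proximalFraction = proximalFraction,
              marks = marks, controlRate = controlRate, nfrWidth = nfrWidth,
              tagLength = tagLength, shift = shift, seed = seed)
  class(cfg) <- "syntheticConfig"
  cfg
}

#' Preset synthetic configurations
#'
#' Named study conditions used throughout the tests:
#' * `"null"` — no planted signal; mark statistically indistinguishable from
#'   the control (calibration).
#' * `"short_range_bimodal"` — flanking-nucleosome peaks at -200/+200 bp.
#' * `"h3k79me2_like"` — one oriented peak at +720 bp (fourth nucleosome
#'   downstream).
#' * `"long_range_unimodal"` — a single broad (sd 1500 bp), weakly enriched
#'   (fold 2) peak, the diffuse long-range behaviour.
#' * `"nfr_occupancy"` — occupancy-like track with the background suppressed
#'   in a 200-bp nucleosome-free region at each site.
#'
#' @param name preset name
#' @param ... overrides passed to [syntheticConfig()] fields
#' @return a `syntheticConfig`
#' @export
syntheticPreset <- function(name = c("null", "short_range_bimodal",
                                     "h3k79me2_like", "long_range_unimodal",
                                     "nfr_occupancy"), ...) {
  name <- match.arg(name)
  spec <- switch(name,
    null = markSpec(fold = 1, enrichedFraction = 0,
                    peakOffsets = numeric(0)),
    short_range_bimodal = markSpec(peakOffsets = c(-200, 200), peakSd = 60,
                                   fold = 25),
    h3k79me2_like = markSpec(peakOffsets = 720, peakSd = 150, fold = 8,
                             oriented = TRUE),
    long_range_unimodal = markSpec(peakOffsets = 0, peakSd = 1500, fold = 2),
    nfr_occupancy = markSpec(fold = 1, enrichedFraction = 0,
                             peakOffsets = numeric(0), nfr = TRUE))
  marks <- stats::setNames(list(spec), name)
  syntheticConfig(marks = marks, ...)
}

.expectedPeakTags <- function(spec) {
  (spec$fold - 1) * spec$backgroundRate * sqrt(2 * pi) * spec$peakSd
}

# uniform event positions in the clamp-free zone [shift, len - shift - 1]
.uniformEvents <- function(n, len, shift) {
  if (n <= 0) return(integer(0))
  as.integer(floor(runif(n, shift, len - shift)))
}

# one GRanges from a named per-chromosome list of event positions; tag
# intervals placed so that shiftTags() recovers the events exactly
.eventsToTags <- function(evList, tagLength, shift) {
  chrom <- rep(names(evList), lengths(evList))
  events <- unlist(evList, use.names = FALSE)
  n <- length(events)
  if (!n) return(GRanges(score = integer(0)))
  str <- sample(c("+", "-"), n, replace = TRUE)
  plus <- str == "+"
  start0 <- ifelse(plus, events - shift, events + shift + 1L - tagLength)
  end0 <- start0 + tagLength
  .sortTags(GRanges(chrom, IRanges(start0 + 1L, end0), strand = str,
                    score = sample(10:40, n, replace = TRUE)))
}

#' Generate a synthetic chromatin dataset
#'
#' Draws, from the single seed in `config`, a genome, gene annotation,
#' binding sites with planted TSS-distance classes and TF roles, per-mark
#' tag sets (uniform Poisson background plus planted peaks at enriched
#' sites), and a structureless matched control.  Tags are emitted as
#' fixed-length stranded intervals placed so that [shiftTags()] with the
#' configured shift recovers the planted event positions exactly.
#'
#' @param config a [syntheticConfig()]
#' @return a list of class `syntheticDataset` with elements `chromSizes`,
#'   `transcripts`, `sites` (incl. planted class, role and orienting gene
#'   strand), `roles`, `tags` (named list of GRanges per mark), `control`
#'   (GRanges), and `truth` (planted enrichment flags and parameters)
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  margin <- 12000
  cs <- stats::setNames(rep(as.integer(config$chromLength), config$nChroms),
                        paste0("chr", seq_len(config$nChroms)))

  ## genes ------------------------------------------------------------------
  gChrom <- sample(names(cs), config$nGenes, replace = TRUE)
  tss <- as.integer(floor(runif(config$nGenes, margin,
                                config$chromLength - margin)))
  gStrand <- ifelse(runif(config$nGenes) < config$minusStrandFraction,
                    "-", "+")
  transcripts <- data.frame(
    gene_id = sprintf("gene_%03d", seq_len(config$nGenes)),
    transcript_id = sprintf("tx_%03d", seq_len(config$nGenes)),
    chrom = gChrom, strand = gStrand, tss = tss,
    exon_bp = sample(500:5000, config$nGenes, replace = TRUE),
    expression = round(rlnorm(config$nGenes, 2, 1), 3),
    stringsAsFactors = FALSE)

  ## sites ------------------------------------------------------------------
  nSites <- config$nTfs * config$sitesPerTf
  tf <- rep(sprintf("TF%02d", seq_len(config$nTfs)),
            each = config$sitesPerTf)
  isProx <- runif(nSites) < config$proximalFraction
  sChrom <- character(nSites); sPos <- integer(nSites)
  tssByChrom <- split(transcripts$tss, transcripts$chrom)
  for (i in seq_len(nSites)) {
    if (isProx[i]) {
      g <- sample.int(config$nGenes, 1L)
      sChrom[i] <- transcripts$chrom[g]
      sPos[i] <- transcripts$tss[g] +
        sample(c(-900:-25, 25:900), 1L)
    } else {
      repeat {
        chr <- sample(names(cs), 1L)
        p <- as.integer(floor(runif(1, margin, config$chromLength - margin)))
        if (min(abs(p - tssByChrom[[chr]])) > 10400) {
          sChrom[i] <- chr; sPos[i] <- p; break
        }
      }
    }
  }
  sites <- data.frame(site_id = sprintf("site_%06d", seq_len(nSites)),
                      chrom = sChrom, pos = sPos, tf = tf, source = "point",
                      planted_class = ifelse(isProx, "proximal", "distal"),
                      stringsAsFactors = FALSE)
  asg <- orientSitesByNearestGene(sites, transcripts)
  sites$gene_strand <- asg$gene_strand
  roles <- data.frame(tf = sprintf("TF%02d", seq_len(config$nTfs)),
                      role = rep_len(c("activator", "repressor"),
                                     config$nTfs),
                      stringsAsFactors = FALSE)
  sites$role <- roles$role[match(sites$tf, roles$tf)]

  ## tags per mark ----------------------------------------------------------
  tagLists <- list()
  enriched <- matrix(FALSE, nSites, length(config$marks),
                     dimnames = list(sites$site_id, names(config$marks)))
  for (mk in names(config$marks)) {
    spec <- config$marks[[mk]]
    evs <- list()
    plantable <- spec$fold > 1 && length(spec$peakOffsets) > 0
    flags <- plantable & (runif(nSites) < spec$enrichedFraction)
    enriched[, mk] <- flags
    if (spec$atSites) {
      pChrom <- sites$chrom; pPos <- sites$pos; pStr <- sites$gene_strand
    } else {
      pChrom <- sample(names(cs), nSites, replace = TRUE)
      pPos <- as.integer(floor(runif(nSites, margin,
                                     config$chromLength - margin)))
      pStr <- rep("+", nSites)
    }
    perPeak <- .expectedPeakTags(spec)
    for (chr in names(cs)) {
      len <- cs[[chr]]
      nBg <- rpois(1, spec$backgroundRate * len)
      ev <- .uniformEvents(nBg, len, config$shift)
      if (spec$nfr) {
        sp <- sort(sites$pos[sites$chrom == chr])
        if (length(sp)) {
          near <- findInterval(ev, sp)
          dLo <- ifelse(near >= 1, abs(ev - sp[pmax(near, 1L)]), Inf)
          dHi <- ifelse(near < length(sp), abs(ev - sp[pmin(near + 1L,
                        length(sp))]), Inf)
          ev <- ev[pmin(dLo, dHi) > config$nfrWidth / 2]
        }
      }
      here <- which(flags & pChrom == chr)
      if (length(here) && perPeak > 0) {
        for (i in here) {
          flip <- if (spec$oriented && identical(pStr[i], "-")) -1 else 1
          for (off in spec$peakOffsets) {
            nP <- rpois(1, perPeak)
            if (nP > 0) {
              e <- pPos[i] + as.integer(round(flip * (off +
                     rnorm(nP, 0, spec$peakSd))))
              e <- pmin(pmax(e, config$shift),
                        len - config$shift - 1L)
              ev <- c(ev, e)
            }
          }
        }
      }
      evs[[chr]] <- ev
    }
    tagLists[[mk]] <- .eventsToTags(evs, config$tagLength, config$shift)
  }

  ## control ----------------------------------------------------------------
  ctrl <- list()
  for (chr in names(cs)) {
    len <- cs[[chr]]
    ctrl[[chr]] <- .uniformEvents(rpois(1, config$controlRate * len), len,
                                  config$shift)
  }
  control <- .eventsToTags(ctrl, config$tagLength, config$shift)

  structure(list(chromSizes = cs, transcripts = transcripts, sites = sites,
                 roles = roles, tags = tagLists, control = control,
                 truth = list(enriched = enriched,
                              planted_class = sites$planted_class,
                              role = sites$role,
                              expected_peak_tags = vapply(config$marks,
                                .expectedPeakTags, numeric(1)),
                              config = config)),
            class = "syntheticDataset")
}

#' Simulate tag sets with a shared latent intensity
#'
#' Generates `nMarks` tag indexes whose per-bin Poisson intensities mix a
#' shared latent gamma field (weight `sharedFraction`) with independent
#' per-mark gamma noise (weight `1 - sharedFraction`), both of unit mean.
#' The genome-bin Spearman correlation between marks increases with
#' `sharedFraction`; at 0 the marks are independent.
#'
#' @param chromSizes named integer vector of chromosome lengths
#' @param sharedFraction weight of the shared field, in `[0, 1]`
#' @param rate mean tag density, tags per bp (default 0.01)
#' @param binSize intensity block size in bp (default 600)
#' @param nMarks number of marks (default 2)
#' @param shape gamma shape of the latent fields (default 1)
#' @param seed integer seed
#' @return named list of [TagIndex-class] (`mark1`, `mark2`, ...)
#' @export
simulateCorrelatedTagSets <- function(chromSizes, sharedFraction, rate = 0.01,
                                      binSize = 600, nMarks = 2, shape = 1,
                                      seed = 1) {
  if (sharedFraction < 0 || sharedFraction > 1)
    stop("sharedFraction must be in [0, 1]")
  set.seed(seed)
  out <- rep(list(stats::setNames(list(), character(0))), nMarks)
  for (chr in names(chromSizes)) {
    len <- chromSizes[[chr]]
    nb <- as.integer(ceiling(len / binSize))
    shared <- rgamma(nb, shape, shape)
    for (m in seq_len(nMarks)) {
      own <- rgamma(nb, shape, shape)
      lam <- rate * binSize *
        (sharedFraction * shared + (1 - sharedFraction) * own)
      counts <- rpois(nb, lam)
      starts <- (seq_len(nb) - 1L) * binSize
      width <- pmin(binSize, len - starts)
      ev <- as.integer(floor(rep(starts, counts) +
                               runif(sum(counts)) * rep(width, counts)))
      out[[m]][[chr]] <- sort(ev)
    }
  }
  stats::setNames(
    lapply(out, tagIndex, chromSizes = chromSizes, source = "mark"),
    paste0("mark", seq_len(nMarks)))
}

#' Write a synthetic dataset to disk in the package's input formats
#'
#' Emits BED6 tag files per mark and for the control, a point-site TSV, a
#' refFlat-like annotation TSV, a TF role TSV and a chrom.sizes file, all
#' readable by the `read*` functions.
#'
#' @param sim a `syntheticDataset` from [simulateDataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, a named list of written paths
#' @export
writeSyntheticData <- function(sim, dir) {
  stopifnot(inherits(sim, "syntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$chrom_sizes <- file.path(dir, "chrom.sizes")
  utils::write.table(data.frame(names(sim$chromSizes), sim$chromSizes),
                     paths$chrom_sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$sites <- file.path(dir, "sites.tsv")
  utils::write.table(sim$sites[, c("chrom", "pos", "tf")], paths$sites,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$roles <- file.path(dir, "roles.tsv")
  utils::write.table(sim$roles, paths$roles, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tx <- sim$transcripts
  span <- pmax(tx$exon_bp, 1000L)
  ann <- data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
                    chrom = tx$chrom, strand = tx$strand,
                    txStart = ifelse(tx$strand == "+", tx$tss,
                                     tx$tss + 1L - span),
                    txEnd = ifelse(tx$strand == "+", tx$tss + span,
                                   tx$tss + 1L),
                    exon_bp = tx$exon_bp, coding = "coding",
                    expression = tx$expression)
  paths$annotation <- file.path(dir, "annotation.tsv")
  utils::write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (mk in names(sim$tags)) {
    paths[[paste0("tags_", mk)]] <- file.path(dir, paste0(mk, ".bed"))
    writeTags(sim$tags[[mk]], paths[[paste0("tags_", mk)]])
  }
  paths$control <- file.path(dir, "control.bed")
  writeTags(sim$control, paths$control)
  invisible(paths)
}
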