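chrSizes <- c(chr1 = 10000L, chr2 = 5000L)

tagsFromBed <- function(...) readTags(writeTempLines(c(...)))

test_that("replicate merging is multiset union with re-sorting", {
  a <- tagsFromBed(bedLine("chr1", c(0, 100, 200), c(36, 136, 236), 30, "+"))
  b <- tagsFromBed(bedLine("chr1", c(50, 150), c(86, 186), 30, "-"))
  m <- mergeReplicates(a, b)
  expect_length(m, 5L)
  expect_equal(GenomicRanges::start(m), c(1L, 51L, 101L, 151L, 201L))
  expect_equal(mergeReplicates(a), a)               # identity
  expect_length(mergeReplicates(a, a), 2L * length(a))  # duplicates kept
  expect_equal(mergeReplicates(list(a, b)), m)      # list form
})

test_that("shifting moves 5' ends 100 bp towards the fragment centre", {
  tags <- tagsFromBed(c(bedLine("chr1", 1000, 1036, 30, "+"),
                        bedLine("chr1", 2000, 2036, 30, "-")))
  ix <- shiftTags(tags, chrSizes, shift = 100)
  expect_equal(tagPositions(ix, "chr1"), c(1100L, 1935L))
  ix0 <- shiftTags(tagsFromBed(bedLine("chr1", 7, 43, 30, "+")),
                   chrSizes, shift = 0)
  expect_equal(tagPositions(ix0, "chr1"), 7L)
  expect_equal(clampedCount(ix), 0L)
})

test_that("off-chromosome shifted events are clamped, counted and conserved", {
  tags <- tagsFromBed(c(bedLine("chr1", 9950, 9986, 30, "+"),   # -> 10050
                        bedLine("chr1", 10, 46, 30, "-")))      # -> -55
  ix <- shiftTags(tags, chrSizes, shift = 100)
  expect_equal(totalCount(ix), 2)                    # conservation
  expect_equal(clampedCount(ix), 2L)
  expect_equal(tagPositions(ix, "chr1"), c(0L, 9999L))
  expect_error(shiftTags(tags, c(chrX = 100L)), "chromSizes")
})

test_that("downsampling is uniform, seed-deterministic and size-checked", {
  ix <- makeIndex(list(chr1 = sort(sample.int(9999, 500)),
                       chr2 = sort(sample.int(4999, 200))), chrSizes)
  expect_equal(downsampleTags(ix, totalCount(ix), seed = 1)@positions,
               ix@positions)                         # exhaustive sample
  expect_equal(totalCount(downsampleTags(ix, 0, seed = 1)), 0)
  d1 <- downsampleTags(ix, 300, seed = 7)
  d2 <- downsampleTags(ix, 300, seed = 7)
  expect_identical(d1@positions, d2@positions)       # determinism
  expect_equal(totalCount(d1), 300)
  expect_error(downsampleTags(ix, 10000, seed = 1), "cannot sample")
})

test_that("window counting matches the worked example and boundary contract", {
  ix <- makeIndex(list(chr1 = c(990L, 1100L, 1460L)), chrSizes)
  cw <- countWindow(ix, "chr1", 1200, 600)           # [900, 1500)
  expect_equal(cw$count, bruteCount(c(990, 1100, 1460), 900, 1500))
  expect_equal(cw$count, 3L)
  expect_equal(cw$effective_window, 600)
  expect_equal(countWindow(makeIndex(list(chr1 = integer(0)), chrSizes),
                           "chr1", 1200, 600)$count, 0L)
  # truncated at chromosome start: [0, 400) only
  trunc <- countWindow(ix, "chr1", 100, 800)
  expect_equal(trunc$effective_window, 500)
  expect_equal(trunc$count, 0L)
  expect_error(countWindow(ix, "chrZ", 10, 100), "unknown chromosome")
  expect_error(countWindow(ix, "chr1", 10, 0), "window")
})

test_that("window counts agree with a brute-force scan and are mirror-invariant", {
  for (seed in 1:5) {
    set.seed(seed)
    ev <- sort(sample.int(9999, 200)) - 1L
    ix <- makeIndex(list(chr1 = ev), chrSizes)
    centers <- sample.int(9999, 25) - 1L
    for (w in c(100, 600, 601)) {
      got <- countWindow(ix, "chr1", centers, w)$count
      lo <- pmax(centers - w %/% 2, 0)
      hi <- pmin(centers - w %/% 2 + w, 10000)
      expect_equal(got, vapply(seq_along(centers), function(i)
        bruteCount(ev, lo[i], hi[i]), numeric(1)))
    }
    # mirror about a pivot far from the edges (keeps windows in-bounds)
    pivot <- 4999L
    keep <- abs(centers - pivot) < 4000
    mirrored <- makeIndex(list(chr1 = sort(2L * pivot - ev)), chrSizes)
    w <- 601  # odd window is symmetric about its centre
    expect_equal(
      countWindow(mirrored, "chr1", 2L * pivot - centers[keep], w)$count,
      countWindow(ix, "chr1", centers[keep], w)$count)
  }
})

test_that("bin counting respects half-open boundaries and conserves events", {
  ix <- makeIndex(list(chr1 = c(0L, 599L, 600L), chr2 = integer(0)),
                  c(chr1 = 1500L, chr2 = 1500L))
  b <- binCounts(ix, 600)
  expect_equal(b@counts$chr1, c(2L, 1L, 0L))         # 3 bins, last truncated
  expect_equal(length(b@counts$chr2), 3L)
  expect_equal(totalCount(b), totalCount(ix))        # conservation
  set.seed(3)
  ix2 <- makeIndex(list(chr1 = sort(sample.int(10000, 700) - 1L)), chrSizes)
  expect_equal(totalCount(binCounts(ix2, 97)), 700)
  out <- tempfile()
  writeBinCounts(b, out)
  tab <- read.delim(out, header = FALSE)
  expect_equal(tab$V4[1:3], c(2L, 1L, 0L))
  expect_equal(tab$V3[3], 1500L)                     # truncated last bin end
})
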