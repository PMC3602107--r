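sizes1 <- c(chr1 = 100000L)

test_that("net profile subtracts the control per position", {
  ev <- list(chr1 = sort(sample.int(100000, 400) - 1L))
  mark <- makeIndex(ev, sizes1)
  ctrl <- makeIndex(ev, sizes1, source = "control")
  sites <- makeSites(c(30000, 60000))
  p <- netSignalProfile(mark, sites, ctrl, flank = 500)
  expect_true(all(p@values == 0))                  # exact cancellation
  pm <- netSignalProfile(mark, sites, NULL, flank = 500)
  pc <- netSignalProfile(mark, sites, makeIndex(list(chr1 = integer(0)),
                                                sizes1, "control"),
                         flank = 500)
  expect_equal(pc@values, pm@values)               # empty control = no-op
})

test_that("a single event appears as a scaled indicator at its offset", {
  mark <- makeIndex(list(chr1 = 50037L), sizes1)
  p <- netSignalProfile(mark, makeSites(50000), flank = 100)
  expect_equal(p@values[p@offsets == 37], 1)
  expect_equal(sum(p@values), 1)
  expect_equal(p@nSites, 1L)
})

test_that("sites truncated by the chromosome edge contribute only defined positions", {
  mark <- makeIndex(list(chr1 = c(5L, 45L)), sizes1)
  p <- netSignalProfile(mark, makeSites(c(10, 50000)), flank = 50)
  # offsets below -10 exist only for the interior site
  expect_equal(p@support[p@offsets < -10], rep(1, 40))
  expect_equal(p@support[p@offsets >= -10], rep(2, 61))
  # the event at 5 (offset -5 of site 1) is averaged over 2 supporting sites
  expect_equal(p@values[p@offsets == -5], 1 / 2)
})

test_that("orientation mirrors minus-strand site profiles before averaging", {
  set.seed(21)
  ev <- list(chr1 = sort(c(30100L + sample(0:50, 20, TRUE),
                           60100L + sample(0:50, 20, TRUE))))
  mark <- makeIndex(ev, sizes1)
  sites <- makeSites(c(30000, 60000))
  un <- netSignalProfile(mark, sites, flank = 300)
  plus <- netSignalProfile(mark, sites, flank = 300,
                           orientStrand = c("+", "+"))
  minus <- netSignalProfile(mark, sites, flank = 300,
                            orientStrand = c("-", "-"))
  expect_equal(plus@values, un@values)             # no reversals
  expect_equal(minus@values, rev(un@values))       # full mirror
  # symmetric input is invariant under orientation
  sym <- makeIndex(list(chr1 = c(29900L, 30100L, 59900L, 60100L)), sizes1)
  s1 <- netSignalProfile(sym, sites, flank = 300)
  s2 <- netSignalProfile(sym, sites, flank = 300,
                         orientStrand = c("-", "+"))
  expect_equal(s2@values, s1@values)
})

test_that("nearest-gene assignment minimises distance with documented ties", {
  tx <- makeTranscripts(tss = c(1000, 5000), strand = c("+", "-"))
  sites <- makeSites(c(1200, 3000, 4800))
  asg <- orientSitesByNearestGene(sites, tx)
  expect_equal(asg$tss, c(1000L, 1000L, 5000L))    # tie at 3000 -> smaller
  expect_equal(asg$gene_strand, c("+", "+", "-"))
  expect_equal(asg$distance, c(200, 2000, 200))
  # signed: downstream in reading direction is positive
  expect_equal(asg$signed_distance, c(200, 2000, 200))
  asgUp <- orientSitesByNearestGene(makeSites(c(800, 5200)), tx)
  expect_equal(asgUp$signed_distance, c(-200, -200))
  expect_error(orientSitesByNearestGene(sites, tx[0, ]), "transcripts")
})

test_that("smoothing is a truncated centred moving average", {
  mk <- function(v) methods::new("SignalProfile",
    offsets = seq_along(v) - 1L - (length(v) %/% 2L), values = v,
    support = rep(1, length(v)), nSites = 1L, smoothing = 0L,
    oriented = FALSE)
  const <- mk(rep(2.5, 501))
  expect_equal(smoothProfile(const, 200)@values, rep(2.5, 501))
  ramp <- mk(seq(0, 1, length.out = 301))
  expect_equal(smoothProfile(ramp, 1)@values, ramp@values)   # identity
  spike <- mk(c(rep(0, 300), 7, rep(0, 300)))
  sm <- smoothProfile(spike, 200)
  inner <- sm@values[sm@values > 0]
  expect_length(inner, 200)                        # plateau of 200 positions
  expect_equal(unique(round(inner, 12)), 7 / 200)
  expect_error(smoothProfile(mk(rep(1, 50)), 100), "larger than")
  # linearity: smooth(aP + bQ) = a smooth(P) + b smooth(Q)
  set.seed(4)
  P <- mk(rnorm(301)); Q <- mk(rnorm(301))
  comb <- mk(2 * P@values - 3 * Q@values)
  expect_equal(smoothProfile(comb, 150)@values,
               2 * smoothProfile(P, 150)@values -
                 3 * smoothProfile(Q, 150)@values)
})

test_that("shape detection finds constructed modes, minima and asymmetry", {
  mk <- function(v) methods::new("SignalProfile",
    offsets = -500:500, values = v, support = rep(1, 1001), nSites = 1L,
    smoothing = 200L, oriented = FALSE)
  off <- -500:500
  bump <- function(c0, s) exp(-(off - c0)^2 / (2 * s^2))
  two <- mk(bump(-200, 50) + bump(200, 50))
  sh <- detectShape(two)
  expect_equal(sh@modeOffsets, c(-200L, 200L))
  expect_equal(sh@interPeakDistance, 400)
  expect_equal(sh@asymmetryIndex, 0, tolerance = 1e-10)
  one <- mk(bump(300, 60))
  sh1 <- detectShape(one)
  expect_equal(sh1@nModes, 1L)
  expect_equal(sh1@modeOffsets, 300L)
  expect_gt(sh1@asymmetryIndex, 0)
  # mirrored input: mirrored modes, negated asymmetry
  shm <- detectShape(mk(rev(bump(300, 60) + 0.4 * bump(-100, 40))))
  shf <- detectShape(mk(bump(300, 60) + 0.4 * bump(-100, 40)))
  expect_equal(shm@modeOffsets, sort(-shf@modeOffsets))
  expect_equal(shm@asymmetryIndex, -shf@asymmetryIndex, tolerance = 1e-10)
  flat <- detectShape(mk(rep(1, 1001)))
  expect_equal(flat@nModes, 0L)
  expect_equal(flat@asymmetryIndex, 0)
  dip <- detectShape(mk(1 - bump(10, 80)))
  expect_equal(dip@minOffset, 10L)
})

test_that("planted bimodal peaks are recovered within smoothing/4", {
  for (d in c(150, 200, 300)) {
    cfg <- syntheticConfig(marks = list(m = markSpec(
      peakOffsets = c(-d, d), peakSd = 50, fold = 25)),
      nGenes = 40, sitesPerTf = 150, nTfs = 2, seed = 100 + d)
    sim <- simulateDataset(cfg)
    mark <- shiftTags(sim$tags$m, sim$chromSizes)
    ctrl <- shiftTags(sim$control, sim$chromSizes, source = "control")
    prof <- smoothProfile(netSignalProfile(mark, sim$sites, ctrl, 1500), 200)
    sh <- detectShape(prof)
    expect_equal(sh@nModes, 2L, label = sprintf("d=%d", d))
    expect_lt(max(abs(sh@modeOffsets - c(-d, d))), 50)
  }
})

test_that("TSS profiles orient by the transcript's own strand", {
  tx <- makeTranscripts(tss = c(20000, 70000), strand = c("+", "-"))
  # mark strictly downstream of both TSSs in reading direction
  mark <- makeIndex(list(chr1 = sort(c(20000L + 300:340,
                                       70000L - 340:300))), sizes1)
  p <- tssProfile(mark, tx, flank = 600)
  expect_true(all(p@values[p@offsets < 0] == 0))   # all mass downstream
  expect_gt(sum(p@values[p@offsets > 0]), 0)
  # plus-strand-only annotation equals the unoriented profile
  txP <- makeTranscripts(tss = c(20000, 70000), strand = "+")
  anchors <- makeSites(c(20000, 70000))
  expect_equal(tssProfile(mark, txP, flank = 600)@values,
               netSignalProfile(mark, anchors, flank = 600)@values)
  # equal planted mass on both sides: near-zero asymmetry
  sym <- makeIndex(list(chr1 = sort(c(20000L + c(-320:-300, 300:320),
                                      70000L + c(-320:-300, 300:320)))),
                   sizes1)
  shp <- detectShape(smoothProfile(tssProfile(sym, tx, flank = 600), 50))
  expect_lt(abs(shp@asymmetryIndex), 0.05)
})
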