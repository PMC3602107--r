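test_that("the genome-wide background rate is the stated arithmetic", {
  expect_equal(lambdaBg(1e7, 2e9, 600), 3.0)
  expect_equal(lambdaBg(0, 2e9, 600), 0)
  expect_equal(lambdaBg(1e7, 2e9, 1200), 2 * lambdaBg(1e7, 2e9, 600))
  expect_error(lambdaBg(1e7, 2e9, 0), "window")
  expect_error(lambdaBg(1e7, 0, 600), "genomeLength")
})

test_that("local lambda components rescale control counts to the window", {
  sizes <- c(chr1 = 100000L)
  # 50 events inside the 1-kb region around pos 50000, none elsewhere
  ev <- sort(as.integer(seq(49510, 50490, length.out = 50)))
  ctrl <- makeIndex(list(chr1 = ev), sizes, source = "control")
  ll <- lambdaLocal(ctrl, "chr1", 50000, 600)
  expect_equal(ll$lambda_1k, 50 * 600 / 1000)        # 30
  expect_equal(ll$lambda_5k, 50 * 600 / 5000)
  expect_equal(ll$lambda_10k, 50 * 600 / 10000)
  expect_equal(ll$lambda_bg, 50 * 600 / 100000)
  expect_equal(ll$lambda_local, 30)
  expect_true(ll$lambda_local >= ll$lambda_bg)
})

test_that("local regions truncated at chromosome ends are rescaled", {
  sizes <- c(chr1 = 100000L)
  ctrl <- makeIndex(list(chr1 = sort(sample.int(3000, 120) - 1L)), sizes,
                    source = "control")
  ll <- lambdaLocal(ctrl, "chr1", 100, 600)
  # 10-kb region is [0, 5100): effective length 5100
  n10 <- bruteCount(tagPositions(ctrl, "chr1"), 0, 5100)
  expect_equal(ll$lambda_10k, n10 * 600 / 5100)
  n1 <- bruteCount(tagPositions(ctrl, "chr1"), 0, 600)
  expect_equal(ll$lambda_1k, n1 * 600 / 600)
})

test_that("empty control degenerates to lambda 0 and threshold 0", {
  sizes <- c(chr1 = 100000L)
  ctrl <- makeIndex(list(chr1 = integer(0)), sizes, source = "control")
  ll <- lambdaLocal(ctrl, "chr1", 50000, 600)
  expect_equal(ll$lambda_local, 0)
  expect_equal(poissonThreshold(ll$lambda_local), 0L)
})

test_that("uniform control gives near-equal lambda components", {
  set.seed(11)
  sizes <- c(chr1 = 1000000L)
  ctrl <- makeIndex(list(chr1 = sort(sample.int(1000000, 50000) - 1L)),
                    sizes, source = "control")
  ll <- lambdaLocal(ctrl, "chr1", 500000, 600)
  # expectation 30 per component; allow 4 sd of the sparsest (1 kb) estimate
  expect_true(all(abs(c(ll$lambda_1k, ll$lambda_5k, ll$lambda_10k) -
                        ll$lambda_bg) < 4 * sqrt(50 * 0.6^2)))
})

test_that("Poisson thresholds equal the pmf-summation oracle on a grid", {
  for (alpha in c(1e-3, 1e-4, 1e-5)) {
    for (lam in c(0, 0.01, 0.1, 0.5, 1, 2, 5, 10, 20, 50, 100)) {
      expect_identical(poissonThreshold(lam, alpha),
                       bruteThreshold(lam, alpha),
                       label = sprintf("lambda=%g alpha=%g", lam, alpha))
    }
  }
  expect_identical(poissonThreshold(5, 1e-4), 15L)
  expect_identical(poissonThreshold(0.1, 1e-4), 3L)
  expect_identical(poissonThreshold(0), 0L)
  lamGrid <- seq(0, 40, by = 0.37)
  expect_true(all(diff(poissonThreshold(lamGrid)) >= 0))  # monotone
  expect_error(poissonThreshold(-1), "non-negative")
  expect_error(poissonThreshold(1, alpha = 0), "alpha")
})

test_that("enrichment is strict: X = t is not enriched, X = t + 1 is", {
  sizes <- c(chr1 = 1000000L)
  # control mass far from the sites: lambda_local = lambda_bg = 2
  ctrl <- makeIndex(list(chr1 = sort(sample.int(50000, 3334) - 1L) + 900000L),
                    sizes, source = "control")
  lam <- lambdaLocal(ctrl, "chr1", 100000, 600)$lambda_local
  t <- poissonThreshold(lam)
  ev <- c(100000L + seq_len(t) * 2L,               # exactly t in window A
          300000L + seq_len(t + 1L) * 2L)          # t + 1 in window B
  mark <- makeIndex(list(chr1 = sort(ev)), sizes)
  calls <- callEnrichment(mark, makeSites(c(100200, 300200)), ctrl)
  expect_equal(calls$observed, c(t, t + 1L))
  expect_equal(calls$threshold, rep(t, 2))
  expect_equal(calls$enriched, c(FALSE, TRUE))
})

test_that("without a control the mark's own background rate is used", {
  sizes <- c(chr1 = 100000L)
  mark <- makeIndex(list(chr1 = sort(sample.int(100000, 1000) - 1L)), sizes)
  expect_message(calls <- callEnrichment(mark, makeSites(50000),
                                         control = NULL), "no control")
  expect_equal(calls$lambda_local, lambdaBg(1000, 100000, 600))
})

test_that("enrichment proportions aggregate and partition consistently", {
  sizes <- c(chr1 = 1000000L)
  set.seed(5)
  sites <- makeSites(seq(100000, 900000, by = 8000))
  # plant a heavy stack of tags at every site: all enriched
  ev <- sort(unlist(lapply(sites$pos, function(p) p + seq(-50, 49))))
  mark <- makeIndex(list(chr1 = ev), sizes)
  ctrl <- makeIndex(list(chr1 = sort(sample.int(1000000, 5000) - 1L)),
                    sizes, source = "control")
  curve <- enrichmentCurve(mark, sites, ctrl, windows = c(200, 600))
  expect_equal(curve$proportion, rep(1.0, 2))
  # group decomposition: overall proportion is the weighted group mean
  grp <- rep(c("a", "b"), length.out = nrow(sites))
  cg <- enrichmentCurve(mark, sites, ctrl, windows = 600, groups = grp)
  all_ <- cg[cg$group == "all", ]
  parts <- cg[cg$group != "all", ]
  expect_equal(all_$proportion,
               sum(parts$proportion * parts$n_sites) / sum(parts$n_sites))
  expect_error(enrichmentCurve(mark, makeSites(integer(0)), ctrl), "empty")
})

test_that("the one-sided binomial site test matches closed forms and oracle", {
  expect_equal(binomialSiteTest(10, 10, 0.5), 0.5^10)
  expect_equal(binomialSiteTest(0, 10, 0.3), 1.0)
  # oracle: direct tail summation
  k <- 37; n <- 100; p0 <- 0.35
  expect_equal(binomialSiteTest(k, n, p0),
               sum(dbinom(k:n, n, p0)))
  expect_gt(binomialSiteTest(35, 100, 0.35), 0.4)   # k ~ n p0 -> p ~ 1/2
  expect_lt(binomialSiteTest(35, 100, 0.35), 0.6)
  expect_error(binomialSiteTest(5, 10, 0), "p0")
})

test_that("decoy-based background proportion is seed-deterministic", {
  sim <- simulateDataset(syntheticPreset("null", sitesPerTf = 10, seed = 2))
  mark <- shiftTags(sim$tags[[1]], sim$chromSizes)
  ctrl <- shiftTags(sim$control, sim$chromSizes, source = "control")
  b1 <- estimateBackgroundProportion(mark, ctrl, nDecoys = 2000, seed = 9)
  b2 <- estimateBackgroundProportion(mark, ctrl, nDecoys = 2000, seed = 9)
  expect_identical(b1, b2)
  expect_lt(b1$p0, 0.01)
})

test_that("paired signed-rank test matches enumeration and symmetry", {
  expect_warning(p <- wilcoxonPaired(1:5 / 5, 1:5 / 5), "zero")
  expect_equal(p, 1)
  a <- (1:10) / 10
  expect_equal(wilcoxonPaired(a + 0.05, a, "greater"), 1 / 2^10)
  # enumeration oracle on an untied random instance
  set.seed(8)
  x <- runif(8); y <- x + rnorm(8, 0.2, 0.3)
  expect_equal(wilcoxonPaired(y, x, "greater"), bruteSignedRank(y - x))
  # swapping the arguments mirrors the one-sided p
  expect_equal(wilcoxonPaired(x, y, "less"),
               wilcoxonPaired(y, x, "greater"))
  # large-n normal approximation agrees with the reference implementation
  xl <- runif(40); yl <- xl + rnorm(40, 0.1, 0.4)
  expect_equal(wilcoxonPaired(yl, xl, "greater"),
               suppressWarnings(wilcox.test(yl, xl, paired = TRUE,
                                            alternative = "greater",
                                            exact = FALSE,
                                            correct = TRUE)$p.value))
  expect_error(wilcoxonPaired(1:3, 1:4), "equal length")
})
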