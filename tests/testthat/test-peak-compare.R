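# Intervals in comments use 0-based half-open coordinates (BED); the
# GRanges literals below are the equivalent 1-based closed form.

test_that("matchPeaks honours the 1-bp overlap and proximity boundary rules", {
  a <- GRanges("chr1", IRanges(101, 200))        # [100,200)
  bOver <- GRanges("chr1", IRanges(200, 300))    # [199,300): 1 bp shared
  m <- matchPeaks(a, bOver, mode = "overlap")
  expect_equal(nrow(m$matches), 1L)
  expect_equal(m$matches$overlapBp, 1L)
  expect_equal(m$matches$gapBp, 0L)

  bAdj <- GRanges("chr1", IRanges(201, 300))     # [200,300): adjacent
  expect_equal(nrow(matchPeaks(a, bAdj, mode = "overlap")$matches), 0L)
  mAdj <- matchPeaks(a, bAdj, mode = "proximity", maxGap = 1000L)
  expect_equal(nrow(mAdj$matches), 1L)
  expect_equal(mAdj$matches$gapBp, 0L)

  aFar <- GRanges("chr1", IRanges(1, 100))       # [0,100)
  bFar <- GRanges("chr1", IRanges(901, 1000))    # [900,1000)
  mFar <- matchPeaks(aFar, bFar, mode = "proximity", maxGap = 1000L)
  expect_equal(mFar$matches$gapBp, 800L)
  expect_equal(nrow(matchPeaks(aFar, bFar, mode = "proximity",
                               maxGap = 799L)$matches), 0L)
})

test_that("shared fractions are 1 for identical sets and 0 for empty sets", {
  x <- grFrom(data.frame(start = c(1, 500, 1200), end = c(100, 700, 1300)))
  m <- matchPeaks(x, x)
  expect_equal(m$sharedFractionA, 1)
  expect_equal(m$sharedFractionB, 1)
  expect_equal(m$sharedFractionUnion, 1)

  e <- matchPeaks(x, GRanges())
  expect_equal(e$sharedFractionA, 0)
  expect_equal(e$sharedFractionB, 0)
  expect_equal(nrow(e$matches), 0L)
})

test_that("matchPeaks equals the brute-force all-pairs matcher", {
  set.seed(77)
  for (rep in 1:12) {
    a <- randomIntervals(sample(50:200, 1))
    b <- randomIntervals(sample(50:200, 1))
    mode <- sample(c("overlap", "proximity"), 1)
    got <- matchPeaks(grFrom(a), grFrom(b), mode = mode)$matches
    ora <- oracleMatch(a, b, mode = mode)
    expect_equal(got$indexA, ora$indexA)
    expect_equal(got$indexB, ora$indexB)
    expect_equal(got$overlapBp, ora$overlapBp)
    expect_equal(got$gapBp, ora$gapBp)
  }
})

test_that("each peak participates in at most one match", {
  set.seed(78)
  a <- randomIntervals(300)
  b <- randomIntervals(300)
  m <- matchPeaks(grFrom(a), grFrom(b), mode = "proximity")$matches
  expect_false(any(duplicated(m$indexA)))
  expect_false(any(duplicated(m$indexB)))
})

test_that("mannWhitney reproduces exact enumeration values", {
  r <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(r$uStatistic, 0)
  expect_equal(r$pValue, 2 / 6)                  # enumeration of C(4,2)
  expect_true(r$exact)

  same <- mannWhitney(c(5, 1, 3), c(3, 1, 5))    # identical multisets
  expect_equal(same$pValue, 1)

  expect_error(mannWhitney(numeric(0), 1), "nonempty")
})

test_that("mannWhitney matches the enumeration oracle on random small samples", {
  set.seed(91)
  for (rep in 1:20) {
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    x <- sample(1:5, nA, replace = TRUE)         # ties on purpose
    y <- sample(1:5, nB, replace = TRUE)
    got <- mannWhitney(x, y)
    ora <- oracleMannWhitney(x, y)
    expect_equal(got$uStatistic, ora$u)
    expect_equal(got$pValue, ora$p)
  }
  # at nA = nB = 8 the exact path engages, so p equals enumeration exactly
  for (rep in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(mannWhitney(x, y)$pValue, oracleMannWhitney(x, y)$p,
                 tolerance = 1e-12)
  }
})

test_that("the tie-corrected normal approximation agrees with wilcox.test", {
  set.seed(92)
  for (rep in 1:15) {
    x <- sample(seq(0, 50, by = 0.5), 25, replace = TRUE)
    y <- sample(seq(0, 50, by = 0.5), 30, replace = TRUE) + rep * 0.3
    got <- mannWhitney(x, y)
    expect_false(got$exact)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$uStatistic, unname(ref$statistic))
    expect_equal(got$pValue, ref$p.value, tolerance = 1e-10)
  }
})

test_that("mannWhitney keeps nominal type-I error and detects 1.5x shifts", {
  set.seed(93)
  nSim <- 10000L
  rejections <- 0L
  for (i in seq_len(nSim)) {
    h <- exp(rnorm(400, sd = 0.6))
    if (mannWhitney(h[1:200], h[201:400])$pValue < 0.05)
      rejections <- rejections + 1L
  }
  expect_lte(rejections / nSim, 0.06)

  # power at a 1.5-fold multiplicative shift with 200 peaks per group
  powerHits <- sum(replicate(50, {
    a <- exp(rnorm(200, sd = 0.6))
    mannWhitney(a, 1.5 * exp(rnorm(200, sd = 0.6)))$pValue < 0.01
  }))
  expect_gte(powerHits, 49)
})

test_that("group summaries report medians, IQRs and inner fences", {
  x <- c(1, 2, 3, 4, 100)
  s <- mannWhitney(x, x + 1)$summary
  expect_equal(s$median[1], 3)
  expect_equal(s$iqr[1], unname(diff(quantile(x, c(0.25, 0.75)))))
  expect_equal(s$upperFence[1],
               unname(quantile(x, 0.75) + 1.5 * s$iqr[1]))
})

test_that("regressHeights recovers slope and intercept on the log scale", {
  h <- c(1, 3.5, 10, 42, 180)
  same <- regressHeights(data.frame(heightA = h, heightB = h))
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0)
  expect_equal(same$r, 1)

  doubled <- regressHeights(data.frame(heightA = h, heightB = 2 * h))
  expect_equal(doubled$slope, 1)
  expect_equal(doubled$intercept, log10(2))

  expect_error(regressHeights(data.frame(heightA = c(5, 5, 5),
                                         heightB = h[1:3])), "constant")
  expect_error(regressHeights(data.frame(heightA = 1, heightB = 2)),
               "at least 2")
  # linear-scale fit is available and exact on linear data
  lin <- regressHeights(data.frame(heightA = h, heightB = 3 * h + 2),
                        log10Scale = FALSE)
  expect_equal(lin$slope, 3)
  expect_equal(lin$intercept, 2)
})
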