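test_that("windowCounts assigns each read to the window holding its start", {
  cs <- c(chr1 = 1000L)
  # ten reads starting inside the first 100-bp window
  r10 <- GRanges("chr1", IRanges(seq(1, 91, by = 10), width = 60))
  wp <- windowCounts(r10, cs)
  expect_equal(profileValues(wp)$chr1, c(10, rep(0, 9)))
  expect_false(isNormalized(wp))

  # a read spanning windows counts once, in its start window
  # (0-based [95, 205) = 1-based start 96, width 110)
  wp2 <- windowCounts(GRanges("chr1", IRanges(96, width = 110)), cs)
  expect_equal(profileValues(wp2)$chr1, c(1, rep(0, 9)))

  # empty input gives an all-zero profile of the right shape
  wp0 <- windowCounts(GRanges(), c(chr1 = 250L), width = 100L)
  expect_equal(profileValues(wp0)$chr1, c(0, 0, 0))

  expect_error(windowCounts(GRanges("chrX", IRanges(1, 10)), cs), "chrX")
})

test_that("window counts conserve the number of reads", {
  set.seed(11)
  cs <- c(chr1 = 5000L, chr2 = 3000L)
  for (rep in 1:5) {
    n <- sample(500, 1)
    chr <- sample(names(cs), n, replace = TRUE)
    st <- floor(runif(n) * (cs[chr] - 80)) + 1L
    reads <- GRanges(chr, IRanges(st, width = 75))
    wp <- windowCounts(reads, cs)
    expect_equal(sum(unlist(profileValues(wp))), n)
  }
})

test_that("normalizeProfile applies the spike/depth/yield formula once", {
  cs <- c(chr1 = 100L)
  wp <- windowCounts(GRanges("chr1", IRanges(rep(1, 50), width = 10)), cs)
  lib <- SpikeInLibrary("a", readsExperimental = 1e6, readsSpike = 2e5)
  # (c/T) * (ref / (s/T)): 50/1e6 * 0.1/0.2 = 2.5e-5
  np <- normalizeProfile(wp, lib, spikeReference = 0.1)
  expect_equal(profileValues(np)$chr1, 2.5e-5)
  expect_true(isNormalized(np))
  expect_error(normalizeProfile(np, lib, 0.1), "already normalized")

  bad <- SpikeInLibrary("b", readsExperimental = 10, readsSpike = 0)
  expect_error(normalizeProfile(wp, bad, 0.1), "spike reads")

  # depth cancels: same material sequenced twice as deep (c, T, s all x2)
  # gives identical normalized values at a fixed reference fraction
})

test_that("normalization is symmetric and invariant to joint rescaling", {
  counts <- c(3, 8, 0, 21, 5)
  p1 <- profileFromCounts(counts, Treads = 1000, s = 200, ref = 150)
  p2 <- profileFromCounts(counts, Treads = 1000, s = 200, ref = 150)
  expect_equal(profileValues(p1), profileValues(p2))

  # doubling counts, T and s jointly leaves normalized values unchanged
  p3 <- profileFromCounts(2 * counts, Treads = 2000, s = 400, ref = 150)
  expect_equal(profileValues(p1), profileValues(p3))
})

test_that("callPeaksSimple finds elevated blocks and merges across gaps", {
  bg <- rep(2L, 100)
  one <- bg; one[40:44] <- 50L
  p <- callPeaksSimple(profileFromCounts(one))
  expect_equal(length(p), 1L)
  expect_equal(c(start(p), end(p)), c(3901L, 4400L))
  expect_equal(mcols(p)$rawHeight, 50)        # raw read-count units

  # two blocks separated by more than mergeGap stay distinct
  two <- bg; two[10:12] <- 40L; two[70:72] <- 40L
  expect_equal(length(callPeaksSimple(profileFromCounts(two))), 2L)
  # within mergeGap (2 windows = 200 bp) they merge
  near <- bg; near[10:12] <- 40L; near[15:17] <- 40L
  expect_equal(length(callPeaksSimple(profileFromCounts(near))), 1L)

  # uniform background yields no peaks, and an all-zero profile none
  expect_equal(length(callPeaksSimple(profileFromCounts(bg))), 0L)
  zero <- profileFromCounts(c(1L, rep(0L, 99)))
  zero@values$chr1[] <- 0
  expect_equal(length(callPeaksSimple(zero)), 0L)

  expect_error(callPeaksSimple(windowCounts(GRanges(), c(chr1 = 100L))),
               "normalized")
})

test_that("runs shorter than minWindows are not called", {
  v <- rep(2L, 60); v[30] <- 80L                  # single hot window
  expect_equal(length(callPeaksSimple(profileFromCounts(v))), 0L)
  expect_equal(length(callPeaksSimple(profileFromCounts(v),
                                      minWindows = 1L)), 1L)
})

test_that("normalizePeakHeights scales raw heights by the spike ratio", {
  pk <- GRanges("chr1", IRanges(c(1, 501), width = 300))
  mcols(pk)$rawHeight <- c(10, 4)
  mcols(pk)$normHeight <- NA_real_
  libEq <- SpikeInLibrary("eq", readsExperimental = 1e5, readsSpike = 500)
  out <- normalizePeakHeights(pk, libEq, spikeReference = 500)
  expect_equal(mcols(out)$normHeight, c(10, 4))   # s == reference: identity

  libHalf <- SpikeInLibrary("h", readsExperimental = 1e5, readsSpike = 1000)
  out2 <- normalizePeakHeights(pk, libHalf, spikeReference = 500)
  expect_equal(mcols(out2)$normHeight, c(5, 2))

  empty <- normalizePeakHeights(callPeaksSimple(
    profileFromCounts(rep(1L, 20))), libEq, 500)
  expect_equal(length(empty), 0L)
})

test_that("between-sample height ratios do not depend on the spike reference", {
  pk <- GRanges("chr1", IRanges(1, 100))
  mcols(pk)$rawHeight <- 12; mcols(pk)$normHeight <- NA_real_
  la <- SpikeInLibrary("a", readsExperimental = 1e5, readsSpike = 300)
  lb <- SpikeInLibrary("b", readsExperimental = 1e5, readsSpike = 900)
  for (ref in c(1, 300, 12345)) {
    ha <- mcols(normalizePeakHeights(pk, la, ref))$normHeight
    hb <- mcols(normalizePeakHeights(pk, lb, ref))$normHeight
    expect_equal(ha / hb, 3)
  }
})

test_that("profiles export as bedGraph and GRanges windows tile the genome", {
  wp <- profileFromCounts(c(0L, 5L, 2L), width = 100L)
  gr <- profileGRanges(wp)
  expect_equal(length(gr), 3L)
  expect_equal(width(gr), rep(100L, 3))
  f <- tempfile(fileext = ".bedGraph")
  writeProfileBedGraph(wp, f)
  back <- rtracklayer::import(f, format = "bedGraph")
  expect_equal(sum(back$score * width(back)) / 100,
               sum(unlist(profileValues(wp))))
})
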