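smallCfg <- function(seed = 1L, ...) {
  SimulationConfig(genomeLength = 1.2e5, nChroms = 2L, nGenes = 60L,
                   nG4 = 15L, nHDNA = 10L, nSTR = 4L, nPeaks = 40L,
                   depth = 20000L, seed = seed, ...)
}

test_that("makeGenome is deterministic and validates its motif plan", {
  g1 <- makeGenome(smallCfg())
  g2 <- makeGenome(smallCfg())
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.character(g1$spikeGenome),
                   as.character(g2$spikeGenome))
  expect_identical(g1$truth, g2$truth)
  expect_false(identical(as.character(g1$genome),
                         as.character(makeGenome(smallCfg(seed = 2))$genome)))

  expect_error(makeGenome(SimulationConfig(genomeLength = 2000,
                                           nG4 = 500L)), "capacity")
})

test_that("background GC content matches the configured value", {
  cfg <- SimulationConfig(genomeLength = 1e6, nChroms = 1L,
                          gcContent = 0.5, nG4 = 10L, nHDNA = 5L,
                          nSTR = 5L, seed = 4)
  g <- makeGenome(cfg)
  s <- as.character(g$genome[[1]])
  gcObs <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcObs - 0.5), 3 * sqrt(0.25 / 1e6) + 0.001)
})

test_that("scanners recover every planted motif", {
  g <- makeGenome(smallCfg(seed = 5))
  truth <- g$truth

  g4 <- scanG4(g$genome)
  tG4 <- truth[mcols(truth)$motifClass == "G4"]
  expect_gte(length(g4), length(tG4))
  # every planted G4 is recovered at exactly its planted interval
  hit <- findOverlaps(tG4, g4, type = "equal", ignore.strand = TRUE)
  expect_equal(length(unique(queryHits(hit))), length(tG4))

  hd <- scanHDNA(g$genome)
  tHD <- truth[mcols(truth)$motifClass == "HDNA"]
  expect_equal(countOverlaps(tHD, hd, ignore.strand = TRUE) > 0,
               rep(TRUE, length(tHD)))

  st <- scanSTR(g$genome, "GAA", minCopies = 4L)
  tST <- truth[mcols(truth)$motifClass == "STR"]
  expect_equal(countOverlaps(tST, st) > 0, rep(TRUE, length(tST)))
})

test_that("gene annotations are non-overlapping and cover every chromosome", {
  cfg <- smallCfg(seed = 6)
  g <- makeGenome(cfg)
  genes <- makeGeneAnnotation(cfg, g$chromSizes)
  expect_equal(length(genes), 60L)
  expect_equal(length(reduce(genes, ignore.strand = TRUE)), 60L)
  expect_setequal(as.character(unique(seqnames(genes))),
                  names(g$chromSizes))
  expect_true(all(end(genes) <= g$chromSizes[as.character(seqnames(genes))]))
})

test_that("emitted reads agree with the truth table within Poisson error", {
  cfg <- smallCfg(seed = 7)
  g <- makeGenome(cfg)
  genes <- makeGeneAnnotation(cfg, g$chromSizes)
  expt <- simulateDripExperiment(cfg, g, genes)
  expect_setequal(names(expt$reads),
                  c("wt", "pp", "wt_rnaseh", "pp_rnaseh"))
  truth <- expt$truth$peaks
  sheet <- expt$sampleSheet

  for (id in c("wt", "pp")) {
    jit <- sheet$jitter[sheet$sampleId == id]
    hts <- if (id == "wt") mcols(truth)$heightWT else mcols(truth)$heightMut
    starts <- GRanges(seqnames(expt$reads[[id]]),
                      IRanges(start(expt$reads[[id]]), width = 1))
    got <- countOverlaps(truth, starts)
    expected <- hts * jit
    # background reads add a small positive excess; 4 Poisson SD + margin
    excess <- cfg@depth * jit * width(truth) / sum(g$chromSizes)
    expect_true(all(abs(got - expected - excess) <
                    4 * sqrt(expected) + 10))
  }

  # RNase H attenuates experimental read counts about 8x
  expect_lt(sheet$T[sheet$sampleId == "wt_rnaseh"] /
            sheet$T[sheet$sampleId == "wt"], 0.25)
  expect_equal(sheet$yieldFactor[sheet$sampleId == "wt_rnaseh"], 1 / 8)
  # spike hybrids are degraded alongside experimental ones
  sPerJit <- sheet$s / sheet$jitter
  sRatio <- sPerJit[sheet$sampleId == "wt_rnaseh"] /
    sPerJit[sheet$sampleId == "wt"]
  expect_lt(abs(sRatio - 1 / 8), 0.05)
})

test_that("mutant elevation is restricted to motif-associated peaks", {
  cfg <- smallCfg(seed = 8)
  g <- makeGenome(cfg)
  genes <- makeGeneAnnotation(cfg, g$chromSizes)
  expt <- simulateDripExperiment(cfg, g, genes)
  pk <- expt$truth$peaks
  assoc <- mcols(pk)$motifAssociated
  expect_true(any(assoc) && any(!assoc))
  expect_equal(mcols(pk)$heightMut[assoc] / mcols(pk)$heightWT[assoc],
               rep(cfg@foldChange, sum(assoc)))
  expect_equal(mcols(pk)$heightMut[!assoc], mcols(pk)$heightWT[!assoc])
})

test_that("fluctuation cohort files are deterministic and round-trip", {
  models <- list(p0 = SwitchingModel(0, nClones = 12, seed = 21),
                 mid = SwitchingModel(0.005, nClones = 12, seed = 22),
                 hi = SwitchingModel(0.02, nClones = 12, seed = 23))
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- simulateFluctuationCohorts(models, outdir = d1)
  c2 <- simulateFluctuationCohorts(models, outdir = d2)
  for (nm in names(models))
    expect_identical(readLines(file.path(d1, paste0(nm, ".tsv"))),
                     readLines(file.path(d2, paste0(nm, ".tsv"))))

  expect_equal(c1$p0$lossFraction, rep(0, 12))
  meds <- vapply(c1, function(x) median(x$lossFraction), numeric(1))
  expect_true(all(diff(meds) > 0))         # medians increase with p

  back <- readFluctuationTsv(attr(c1, "files"))
  expect_equal(back$mid, c1$mid$lossFraction)
})

test_that("the full synthetic pipeline reproduces the planted biology", {
  res <- runSyntheticPipeline(SimulationConfig(genomeLength = 4e5,
      nChroms = 1L, nGenes = 200L, nG4 = 25L, nHDNA = 15L, nSTR = 5L,
      nPeaks = 120L, depth = 30000L, seed = 31))
  # peaks in both conditions coincide in position
  expect_gt(res$match$sharedFractionA, 0.9)
  # heights are higher in the mutant, but only at motif-associated peaks
  mm <- res$match$matches
  assoc <- countOverlaps(res$peaks[[1]][mm$indexA], res$genome$truth) > 0
  expect_gt(median(mm$heightB[assoc] / mm$heightA[assoc]), 1.5)
  expect_lt(abs(median(mm$heightB[!assoc] / mm$heightA[!assoc]) - 1), 0.2)
  expect_lt(res$heightTest$pValue, 0.01)
  # peak-bearing genes are enriched for planted motifs
  expect_lt(res$enrichment$pValue, 0.01)
  expect_gt(res$enrichment$foldEnrichment, 1.2)
})
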