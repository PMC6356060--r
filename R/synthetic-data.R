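## Synthetic-data generation with recorded ground truth: planted-motif
## genomes, gene annotations, two-condition spike-in read sets with
## motif-linked height differences, RNase H controls, and fluctuation
## cohorts.  Everything is deterministic given the config seed.

## slot width reserved per planted motif plus its T buffers; G4 max span
## is 4*5 + 3*7 = 41 bp, mirror arms 2*12 + 6.  The 8-bp T buffer exceeds
## the maximum G4 loop, so background G-runs can never chain into a
## planted motif and steal its leftmost match
.MOTIF_SLOT <- 90L
.MOTIF_BUFFER <- 8L

#' Generate a synthetic genome with planted structure-forming motifs
#'
#' Background sequence is i.i.d. at the configured GC content.  Motifs are
#' planted at non-overlapping slots: G4 instances sampled from the
#' four-G-run grammar (G-runs of 3-5, loops of 1-7 drawn from A/C/T so the
#' planted span is exactly the scanned span), H-DNA instances as perfect
#' homopurine mirror repeats, and (unit)n tandem tracts.  Each insert is
#' buffered with 8 bp of T -- longer than the widest G4 loop -- so planted
#' intervals are recovered exactly by the scanners and never merge with
#' background matches.  A disjoint spike genome is generated separately.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `genome` (DNAStringSet), `spikeGenome`
#'   (DNAStringSet, chromosome `"spike_1"`), `chromSizes`,
#'   `spikeChromSizes`, and `truth` -- a [GenomicRanges::GRanges] of
#'   planted motifs with `motifClass` metadata.
#' @examples
#' g <- makeGenome(SimulationConfig(genomeLength = 5e4, nG4 = 5,
#'                                  nHDNA = 5, nSTR = 2, seed = 1))
#' length(scanG4(g$genome))   # >= 5
#' @seealso [simulateDripExperiment()]
#' @export
makeGenome <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, {
    chromLen <- rep(config@genomeLength %/% config@nChroms, config@nChroms)
    names(chromLen) <- paste0("chr", seq_len(config@nChroms))
    nMotifs <- c(G4 = config@nG4, HDNA = config@nHDNA, STR = config@nSTR)
    slotsPerChrom <- chromLen %/% .MOTIF_SLOT
    if (sum(nMotifs) > sum(slotsPerChrom))
      stop("motif plan (", sum(nMotifs), " motifs) exceeds genome capacity (",
           sum(slotsPerChrom), " slots)")
    gc <- config@gcContent
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(chromLen, function(L)
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    ## assign each motif a (chrom, slot)
    slotChrom <- rep(names(chromLen), slotsPerChrom)
    slotIdx <- unlist(lapply(slotsPerChrom, seq_len), use.names = FALSE)
    pick <- sample(length(slotChrom), sum(nMotifs))
    cls <- rep(names(nMotifs), nMotifs)
    hits <- vector("list", sum(nMotifs))
    for (i in seq_along(pick)) {
      ins <- switch(cls[i],
        G4 = .sampleG4(),
        HDNA = .sampleHDNA(),
        STR = strrep(config@strUnit, config@strCopies))
      cn <- slotChrom[pick[i]]
      at <- (slotIdx[pick[i]] - 1L) * .MOTIF_SLOT + 2L   # 1-based
      buf <- strrep("T", .MOTIF_BUFFER)
      piece <- paste0(buf, ins, buf)
      substr(seqs[[cn]], at, at + nchar(piece) - 1L) <- piece
      hits[[i]] <- GRanges(cn, IRanges(at + .MOTIF_BUFFER,
                                       at + .MOTIF_BUFFER + nchar(ins) - 1L),
                           motifClass = cls[i])
    }
    truth <- sort(suppressWarnings(do.call(c, hits)), ignore.strand = TRUE)
    spike <- paste(sample(names(probs), config@spikeGenomeLength,
                          replace = TRUE, prob = probs), collapse = "")
    list(genome = DNAStringSet(setNames(seqs, names(chromLen))),
         spikeGenome = DNAStringSet(c(spike_1 = spike)),
         chromSizes = chromLen,
         spikeChromSizes = c(spike_1 = config@spikeGenomeLength),
         truth = truth)
  })
}

## one G4 instance from the regex grammar; loops avoid G so the planted
## interval is exactly the maximal match
.sampleG4 <- function() {
  runs <- strrep("G", sample(3:5, 4, replace = TRUE))
  loops <- vapply(sample(1:7, 3, replace = TRUE), function(L)
    paste(sample(c("A", "C", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  paste0(runs[1], loops[1], runs[2], loops[2], runs[3], loops[3], runs[4])
}

## one perfect homopurine mirror repeat (arm + spacer + reversed arm)
.sampleHDNA <- function() {
  arm <- sample(c("A", "G"), sample(8:12, 1), replace = TRUE)
  spacer <- paste(sample(c("A", "G"), sample(0:4, 1), replace = TRUE),
                  collapse = "")
  paste0(paste(arm, collapse = ""), spacer, paste(rev(arm), collapse = ""))
}

#' Generate a non-overlapping gene annotation over a synthetic genome
#'
#' Tiles `nGenes` genes evenly over the chromosomes, each occupying about
#' 60% of its tile with random strand, leaving intergenic space for
#' extragenic peaks.
#'
#' @inheritParams makeGenome
#' @param chromSizes named vector of chromosome lengths (from
#'   [makeGenome()]).
#' @return a [GenomicRanges::GRanges] with `gene_id` metadata, stranded.
#' @export
makeGeneAnnotation <- function(config, chromSizes) {
  stopifnot(is(config, "SimulationConfig"))
  .withSeed(config@seed + 1L, {
    perChrom <- table(rep(seq_along(chromSizes),
                          length.out = config@nGenes))
    out <- lapply(seq_along(chromSizes), function(ci) {
      ng <- as.integer(perChrom[as.character(ci)])
      if (is.na(ng) || ng == 0L) return(NULL)
      tile <- chromSizes[[ci]] %/% ng
      glen <- max(200L, as.integer(tile * 0.6))
      st <- (seq_len(ng) - 1L) * tile + as.integer(tile * 0.2) + 1L
      GRanges(names(chromSizes)[ci],
              IRanges(st, width = pmin(glen, chromSizes[[ci]] - st + 1L)),
              strand = sample(c("+", "-"), ng, replace = TRUE))
    })
    genes <- suppressWarnings(do.call(c, out[!vapply(out, is.null, TRUE)]))
    mcols(genes)$gene_id <- sprintf("gene%05d", seq_along(genes))
    genes
  })
}

#' Simulate a two-condition spike-in DRIP experiment
#'
#' Emits four libraries (wildtype/primpol, untreated/RNase H-treated) of
#' fixed-length single-end read intervals with known truth.  True peaks
#' are placed either centred on planted motifs (`fracMotifPeaks` of them)
#' or inside genes, each gene receiving a peak independently with a
#' probability `relativeRisk`-fold higher for motif-bearing genes (the
#' configured value is exactly the per-gene relative risk); the mutant's
#' expected peak height is `baseHeight * foldChange`
#' at motif-associated peaks and `baseHeight` elsewhere.  Per library,
#' background reads are uniform, per-peak read counts are Poisson with
#' mean proportional to the true height times a shared multiplicative
#' depth jitter, and spike-genome reads are Poisson with mean
#' (wild-type expected material / `spikeCellRatio`) times the same
#' jitter -- condition-independent, as spike material per cell is.  RNase H
#' treatment degrades experimental and spike hybrids alike, so RNase H
#' libraries have experimental AND spike signal divided by
#' `rnaseHAttenuation`, with `yieldFactor = 1/rnaseHAttenuation`
#' recording the measured nucleic-acid recovery that the read
#' composition alone cannot see.
#'
#' @inheritParams makeGenome
#' @param genome the list returned by [makeGenome()].
#' @param genes gene annotation from [makeGeneAnnotation()].
#' @param peakWidth true peak width in bp (default 800).
#' @param jitterRange range of the per-library uniform depth jitter
#'   (default `c(0.6, 1.6)`).
#' @return list with `reads` (named list of GRanges, one per library),
#'   `sampleSheet` (data.frame: sampleId, condition, treatment, T, s,
#'   yieldFactor, jitter), `libraries` (list of
#'   [SpikeInLibrary-class]), and `truth` (list: `peaks` GRanges with
#'   `motifAssociated`, `heightWT`, `heightMut`; `motifGenes` character).
#' @export
simulateDripExperiment <- function(config, genome, genes, peakWidth = 800L,
                                   jitterRange = c(0.6, 1.6)) {
  stopifnot(is(config, "SimulationConfig"))
  .withSeed(config@seed + 2L, {
    chromSizes <- genome$chromSizes
    motifs <- genome$truth
    motifGenes <- genesWithFeature(genes, motifs)$geneIds
    isMotifGene <- .geneIds(genes) %in% motifGenes

    ## --- true peak placement ---------------------------------------------
    nMotifPeaks <- min(round(config@nPeaks * config@fracMotifPeaks),
                       length(motifs))
    peakList <- list()
    if (nMotifPeaks > 0) {
      sel <- sample(length(motifs), nMotifPeaks)
      ctr <- (start(motifs)[sel] + end(motifs)[sel]) %/% 2L
      peakList[[1]] <- GRanges(seqnames(motifs)[sel],
                               IRanges(ctr - peakWidth %/% 2L,
                                       width = peakWidth))
    }
    nGenePeaks <- config@nPeaks - nMotifPeaks
    if (nGenePeaks > 0) {
      ## per-gene Bernoulli placement so the relative risk is exactly the
      ## ratio of per-gene peak probabilities (weighted sampling without
      ## replacement would compress it at high sampling fractions)
      w <- ifelse(isMotifGene, config@relativeRisk, 1)
      p0 <- nGenePeaks / sum(w)
      gi <- which(runif(length(genes)) < pmin(1, p0 * w))
      ctr <- start(genes)[gi] +
        floor(runif(length(gi)) * width(genes)[gi])
      peakList[[2]] <- GRanges(seqnames(genes)[gi],
                               IRanges(ctr - peakWidth %/% 2L,
                                       width = peakWidth))
    }
    peakList <- peakList[!vapply(peakList, is.null, TRUE)]
    peaks <- suppressWarnings(do.call(c, peakList))
    start(peaks) <- pmax(1L, start(peaks))
    end(peaks) <- pmin(end(peaks), chromSizes[as.character(seqnames(peaks))])
    ## greedy drop of overlapping true peaks (keep first)
    peaks <- peaks[order(as.character(seqnames(peaks)), start(peaks))]
    keep <- !logical(length(peaks))
    lastEnd <- -Inf; lastChr <- ""
    for (i in seq_along(peaks)) {
      cn <- as.character(seqnames(peaks))[i]
      if (cn == lastChr && start(peaks)[i] <= lastEnd + 1L) {
        keep[i] <- FALSE
      } else {
        lastChr <- cn; lastEnd <- end(peaks)[i]
      }
    }
    peaks <- peaks[keep]
    motifAssoc <- countOverlaps(peaks, motifs, ignore.strand = TRUE) > 0L
    mcols(peaks)$motifAssociated <- motifAssoc
    mcols(peaks)$heightWT <- rep(config@baseHeight, length(peaks))
    mcols(peaks)$heightMut <- config@baseHeight *
      ifelse(motifAssoc, config@foldChange, 1)

    ## --- read simulation --------------------------------------------------
    libs <- expand.grid(condition = c("wildtype", "primpol"),
                        treatment = c("untreated", "rnaseh"),
                        stringsAsFactors = FALSE)
    libs$sampleId <- paste0(ifelse(libs$condition == "wildtype", "wt", "pp"),
                            ifelse(libs$treatment == "rnaseh", "_rnaseh", ""))
    readsList <- list(); sheet <- list(); libObjs <- list()
    for (i in seq_len(nrow(libs))) {
      cond <- libs$condition[i]; trt <- libs$treatment[i]
      jit <- runif(1, jitterRange[1], jitterRange[2])
      att <- if (trt == "rnaseh") config@rnaseHAttenuation else 1
      hts <- if (cond == "wildtype") mcols(peaks)$heightWT
             else mcols(peaks)$heightMut
      expBg <- config@depth * jit / att
      expPeak <- hts * jit / att
      ## background reads: uniform starts across chromosomes
      nBg <- rpois(1, expBg)
      bgChr <- sample(names(chromSizes), nBg, replace = TRUE,
                      prob = chromSizes / sum(chromSizes))
      bgStart <- floor(runif(nBg) *
                       (chromSizes[bgChr] - config@readLength)) + 1L
      ## peak reads: uniform starts within each peak
      nPk <- rpois(length(peaks), expPeak)
      pkChr <- rep(as.character(seqnames(peaks)), nPk)
      pkStart <- unlist(lapply(seq_along(peaks), function(j) {
        if (nPk[j] == 0L) return(integer(0))
        start(peaks)[j] +
          floor(runif(nPk[j]) * (width(peaks)[j] - 1L))
      }), use.names = FALSE)
      rd <- GRanges(c(bgChr, pkChr),
                    IRanges(c(bgStart, pkStart), width = config@readLength))
      rd <- rd[sample(length(rd))]      # shuffle, as an aligner would emit
      end(rd) <- pmin(end(rd), chromSizes[as.character(seqnames(rd))])
      ## spike material per cell is condition-independent; spike reads
      ## scale only with the library's sequencing-depth jitter
      spikeBase <- (config@depth + sum(mcols(peaks)$heightWT)) /
        config@spikeCellRatio
      s <- rpois(1, spikeBase * jit / att)
      yf <- if (trt == "rnaseh") 1 / config@rnaseHAttenuation else 1
      readsList[[libs$sampleId[i]]] <- rd
      libObjs[[libs$sampleId[i]]] <-
        SpikeInLibrary(libs$sampleId[i], cond, trt,
                       readsExperimental = length(rd), readsSpike = s,
                       yieldFactor = yf)
      sheet[[i]] <- data.frame(sampleId = libs$sampleId[i],
                               condition = cond, treatment = trt,
                               T = length(rd), s = s, yieldFactor = yf,
                               jitter = jit)
    }
    list(reads = readsList, sampleSheet = do.call(rbind, sheet),
         libraries = libObjs,
         truth = list(peaks = peaks, motifGenes = motifGenes))
  })
}

#' Simulate fluctuation cohorts for a set of switching models
#'
#' Runs [simulateCohort()] for each model and optionally writes one TSV
#' per group (columns `cloneId`, `lossFraction`, `nCellsSampled`).
#'
#' @param models named list of [SwitchingModel-class] objects.
#' @param outdir optional directory for the TSV files.
#' @return named list of cohort data.frames (invisibly returns file paths
#'   as the `"files"` attribute when `outdir` is given).
#' @export
simulateFluctuationCohorts <- function(models, outdir = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (is.null(names(models)))
    names(models) <- paste0("group", seq_along(models))
  out <- lapply(models, simulateCohort)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(names(out), function(nm) {
      f <- file.path(outdir, paste0(nm, ".tsv"))
      write.table(out[[nm]], f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f
    }, character(1))
    attr(out, "files") <- files
  }
  out
}

#' Run the full synthetic pipeline end to end
#'
#' Convenience driver used by examples and validation: generates the
#' genome, genes and reads, builds normalized profiles, calls peaks in
#' both untreated conditions, normalizes peak heights, matches peaks,
#' compares matched heights, and tests motif enrichment of peak-bearing
#' genes.
#'
#' @inheritParams makeGenome
#' @return list with `genome`, `genes`, `experiment`, `profiles`
#'   (normalized WindowProfiles), `peaks` (named list of peak GRanges for
#'   the untreated libraries), `match` (from [matchPeaks()]),
#'   `heightTest` (Mann-Whitney on matched heights), `enrichment`
#'   (from [enrichmentTable()], G4+H-DNA motifs vs wild-type peaks), and
#'   `truth`.
#' @examples
#' \donttest{
#' res <- runSyntheticPipeline(SimulationConfig(genomeLength = 2e5,
#'     nGenes = 100, nPeaks = 60, depth = 20000, seed = 3))
#' res$enrichment$pValue
#' }
#' @export
runSyntheticPipeline <- function(config) {
  genome <- makeGenome(config)
  genes <- makeGeneAnnotation(config, genome$chromSizes)
  expt <- simulateDripExperiment(config, genome, genes)
  spikeFrac <- batchSpikeFraction(expt$libraries)
  spikeRef <- batchSpikeReads(expt$libraries)
  profiles <- lapply(names(expt$reads), function(nm) {
    wp <- windowCounts(expt$reads[[nm]], genome$chromSizes,
                       sampleId = nm)
    normalizeProfile(wp, expt$libraries[[nm]], spikeFrac)
  })
  names(profiles) <- names(expt$reads)
  untreated <- names(which(vapply(expt$libraries, treatment,
                                  character(1)) == "untreated"))
  peaks <- lapply(untreated, function(nm)
    normalizePeakHeights(callPeaksSimple(profiles[[nm]]),
                         expt$libraries[[nm]], spikeRef))
  names(peaks) <- untreated
  wtId <- untreated[vapply(expt$libraries[untreated], condition,
                           character(1)) == "wildtype"]
  ppId <- setdiff(untreated, wtId)
  match <- matchPeaks(peaks[[wtId]], peaks[[ppId]])
  heightTest <- if (nrow(match$matches) >= 2L)
    mannWhitney(match$matches$heightA, match$matches$heightB)
  enr <- enrichmentTable(genes, genome$truth, peaks[[wtId]])
  list(genome = genome, genes = genes, experiment = expt,
       profiles = profiles, peaks = peaks, match = match,
       heightTest = heightTest, enrichment = enr,
       truth = expt$truth)
}
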