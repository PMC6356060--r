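#' SpikeInLibrary: per-library read accounting for spike-in normalization
#'
#' Records, for one sequencing library, the uniquely mapped read counts on the
#' experimental genome and on the spike genome, the biological condition and
#' RNase H treatment status, and the relative nucleic-acid recovery
#' (`yieldFactor`) compared with the matched untreated sample.  The yield
#' factor feeds the RNase H correction: treated samples recover at least
#' eightfold less material, so their default factor is 1/8.
#'
#' @slot sampleId character, unique library label.
#' @slot condition character, one of `"wildtype"`, `"primpol"`, `"other"`.
#' @slot treatment character, `"untreated"` or `"rnaseh"`.
#' @slot readsExperimental numeric, uniquely mapped experimental-genome reads.
#' @slot readsSpike numeric, uniquely mapped spike-genome reads.
#' @slot yieldFactor numeric in (0, 1], relative recovery vs untreated.
#'
#' @examples
#' SpikeInLibrary("wt1", "wildtype", readsExperimental = 1e6, readsSpike = 2e5)
#' @export
setClass("SpikeInLibrary",
  representation(sampleId = "character", condition = "character",
                 treatment = "character", readsExperimental = "numeric",
                 readsSpike = "numeric", yieldFactor = "numeric"))

setValidity("SpikeInLibrary", function(object) {
  msg <- character(0)
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single nonempty string")
  if (!object@condition %in% c("wildtype", "primpol", "other"))
    msg <- c(msg, "condition must be 'wildtype', 'primpol' or 'other'")
  if (!object@treatment %in% c("untreated", "rnaseh"))
    msg <- c(msg, "treatment must be 'untreated' or 'rnaseh'")
  if (object@readsExperimental < 0)
    msg <- c(msg, "readsExperimental must be >= 0")
  if (object@readsSpike < 0)
    msg <- c(msg, "readsSpike must be >= 0")
  if (object@yieldFactor <= 0)
    msg <- c(msg, "yieldFactor must be > 0")
  if (object@treatment == "rnaseh" && object@yieldFactor > 1)
    msg <- c(msg, "RNase H-treated libraries must have yieldFactor <= 1")
  if (length(msg)) msg else TRUE
})

#' @param sampleId,condition,treatment,readsExperimental,readsSpike,yieldFactor
#'   see slots.
#' @rdname SpikeInLibrary-class
#' @export
SpikeInLibrary <- function(sampleId, condition = "other",
                           treatment = "untreated",
                           readsExperimental, readsSpike,
                           yieldFactor = if (treatment == "rnaseh") 1 / 8 else 1) {
  new("SpikeInLibrary", sampleId = sampleId, condition = condition,
      treatment = treatment,
      readsExperimental = as.numeric(readsExperimental),
      readsSpike = as.numeric(readsSpike),
      yieldFactor = as.numeric(yieldFactor))
}

setMethod("show", "SpikeInLibrary", function(object) {
  cat("SpikeInLibrary '", object@sampleId, "' (", object@condition, ", ",
      object@treatment, ")\n", sep = "")
  cat("  experimental reads:", format(object@readsExperimental, big.mark = ","),
      " spike reads:", format(object@readsSpike, big.mark = ","),
      " yield factor:", object@yieldFactor, "\n")
})

#' WindowProfile: fixed-width per-window signal track for one library
#'
#' Signal values over non-overlapping fixed-width windows tiling each
#' chromosome (default 100 bp, the resolution used for normalized display
#' profiles).  Window `i` (1-based) of a chromosome covers the 0-based
#' half-open interval `[(i-1)*w, i*w)`.  `normalized` records whether the
#' spike-in/depth/yield normalization has been applied; it may be applied
#' only once.
#'
#' @slot values named list, one numeric vector of per-window values per
#'   chromosome.
#' @slot windowWidth integer, window width in bp.
#' @slot chromSizes named integer, chromosome lengths in bp.
#' @slot normalized logical flag.
#' @slot normFactor numeric, the linear factor the normalization applied
#'   to the raw counts (1 for a raw profile); lets downstream code relate
#'   normalized values back to read counts.
#' @slot sampleId character label (may be `NA`).
#' @export
setClass("WindowProfile",
  representation(values = "list", windowWidth = "integer",
                 chromSizes = "integer", normalized = "logical",
                 normFactor = "numeric", sampleId = "character"))

setValidity("WindowProfile", function(object) {
  msg <- character(0)
  if (object@windowWidth < 1L) msg <- c(msg, "windowWidth must be >= 1")
  if (is.null(names(object@chromSizes)) ||
      !identical(sort(names(object@values)), sort(names(object@chromSizes))))
    msg <- c(msg, "values and chromSizes must cover the same chromosomes")
  else {
    expect <- ceiling(object@chromSizes / object@windowWidth)
    got <- lengths(object@values)[names(object@chromSizes)]
    if (!all(got == expect))
      msg <- c(msg, "each chromosome needs ceiling(length/width) windows")
    if (any(unlist(object@values, use.names = FALSE) < 0))
      msg <- c(msg, "window values must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "WindowProfile", function(object) {
  cat("WindowProfile (", if (object@normalized) "normalized" else "raw",
      "), ", length(object@chromSizes), " chromosome(s), ",
      object@windowWidth, "-bp windows\n", sep = "")
  cat("  total signal:", sum(unlist(object@values, use.names = FALSE)), "\n")
})

#' SwitchingModel: irreversible per-division epigenetic switching
#'
#' Parameters of the clonal fluctuation-assay model: a clone grows from a
#' single expressing ("high") cell by synchronous doublings; at every
#' division each daughter of a high cell independently converts to the
#' silenced ("low") state with probability `pSwitch`, and the low state is
#' absorbing.  After `nDivisions` divisions the loss-variant fraction of the
#' clone is scored, optionally through binomial subsampling of
#' `nCellsSampled` cells to emulate flow-cytometry counting.
#'
#' @slot pSwitch numeric in \[0, 1\], per-division conversion probability.
#' @slot nDivisions integer >= 0.
#' @slot nClones integer >= 1, clones per cohort.
#' @slot nCellsSampled integer, cells scored per clone (`NA` = exact
#'   fraction).
#' @slot seed integer RNG seed (`NA` = use current RNG state).
#'
#' @examples
#' simulateCohort(SwitchingModel(0.01, nClones = 5, seed = 1))
#' @export
setClass("SwitchingModel",
  representation(pSwitch = "numeric", nDivisions = "integer",
                 nClones = "integer", nCellsSampled = "integer",
                 seed = "integer"))

setValidity("SwitchingModel", function(object) {
  msg <- character(0)
  if (object@pSwitch < 0 || object@pSwitch > 1)
    msg <- c(msg, "pSwitch must be in [0, 1]")
  if (object@nDivisions < 0L) msg <- c(msg, "nDivisions must be >= 0")
  if (object@nClones < 1L) msg <- c(msg, "nClones must be >= 1")
  if (!is.na(object@nCellsSampled) && object@nCellsSampled < 1L)
    msg <- c(msg, "nCellsSampled must be >= 1 or NA")
  if (length(msg)) msg else TRUE
})

#' @param pSwitch,nDivisions,nClones,nCellsSampled,seed see slots.  The
#'   default of 40 divisions corresponds to 17--20 days of culture at a
#'   10--12 h doubling time.
#' @rdname SwitchingModel-class
#' @export
SwitchingModel <- function(pSwitch, nDivisions = 40L, nClones = 24L,
                           nCellsSampled = NA_integer_, seed = NA_integer_) {
  new("SwitchingModel", pSwitch = as.numeric(pSwitch),
      nDivisions = as.integer(nDivisions), nClones = as.integer(nClones),
      nCellsSampled = as.integer(nCellsSampled), seed = as.integer(seed))
}

setMethod("show", "SwitchingModel", function(object) {
  cat("SwitchingModel: p_switch =", object@pSwitch, "over",
      object@nDivisions, "divisions,", object@nClones, "clones\n")
  cat("  expected loss fraction:",
      signif(1 - (1 - object@pSwitch)^object@nDivisions, 4), "\n")
})

#' SimulationConfig: ground-truth synthetic experiment design
#'
#' One object holds every knob of the synthetic study: the planted-motif
#' genome, gene annotation, two-condition spike-in read sets with
#' motif-linked height differences, RNase H controls, and the spike-in
#' design.  Defaults mirror the assay design the pipeline targets: a
#' Drosophila-style spike genome at a 1:4.2 cell ratio and at least
#' eightfold signal attenuation after RNase H treatment.
#'
#' @slot genomeLength integer, total experimental genome length (bp).
#' @slot nChroms integer, chromosomes the genome is split into.
#' @slot gcContent numeric in (0, 1), background GC fraction.
#' @slot nG4,nHDNA,nSTR integers, planted motif counts per class.
#' @slot strUnit character, tandem-repeat unit; `strCopies` integer copies.
#' @slot nGenes integer, genes tiled over the genome.
#' @slot nPeaks integer, true peaks.
#' @slot fracMotifPeaks numeric, fraction of peaks placed at planted motifs.
#' @slot baseHeight numeric, expected reads per peak in the wild type.
#' @slot foldChange numeric, mutant/wild-type height ratio at
#'   motif-associated peaks (elsewhere 1).
#' @slot relativeRisk numeric, relative risk of peak placement in
#'   motif-bearing genes (drives the enrichment signal).
#' @slot depth integer, background reads per library.
#' @slot readLength integer, simulated single-end read length (bp).
#' @slot spikeCellRatio numeric, spike:experimental cell ratio denominator
#'   (4.2 means 1:4.2).
#' @slot spikeGenomeLength integer, spike genome length (bp).
#' @slot rnaseHAttenuation numeric >= 1, fold signal loss after RNase H.
#' @slot seed integer master seed.
#' @export
setClass("SimulationConfig",
  representation(genomeLength = "integer", nChroms = "integer",
                 gcContent = "numeric", nG4 = "integer", nHDNA = "integer",
                 nSTR = "integer", strUnit = "character",
                 strCopies = "integer", nGenes = "integer",
                 nPeaks = "integer", fracMotifPeaks = "numeric",
                 baseHeight = "numeric", foldChange = "numeric",
                 relativeRisk = "numeric", depth = "integer",
                 readLength = "integer", spikeCellRatio = "numeric",
                 spikeGenomeLength = "integer",
                 rnaseHAttenuation = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  pos <- c(genomeLength = object@genomeLength, nChroms = object@nChroms,
           nGenes = object@nGenes, nPeaks = object@nPeaks,
           baseHeight = object@baseHeight, depth = object@depth,
           readLength = object@readLength,
           spikeCellRatio = object@spikeCellRatio,
           spikeGenomeLength = object@spikeGenomeLength)
  if (any(pos <= 0))
    msg <- c(msg, paste("must be positive:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@gcContent <= 0 || object@gcContent >= 1)
    msg <- c(msg, "gcContent must be in (0, 1)")
  if (object@fracMotifPeaks < 0 || object@fracMotifPeaks > 1)
    msg <- c(msg, "fracMotifPeaks must be in [0, 1]")
  if (object@foldChange <= 0) msg <- c(msg, "foldChange must be > 0")
  if (object@relativeRisk <= 0) msg <- c(msg, "relativeRisk must be > 0")
  if (object@rnaseHAttenuation < 1)
    msg <- c(msg, "rnaseHAttenuation must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param genomeLength,nChroms,gcContent,nG4,nHDNA,nSTR,strUnit,strCopies
#'   see slots.
#' @param nGenes,nPeaks,fracMotifPeaks,baseHeight,foldChange,relativeRisk
#'   see slots.
#' @param depth,readLength,spikeCellRatio,spikeGenomeLength,rnaseHAttenuation,seed
#'   see slots.
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(genomeLength = 1e6, nChroms = 2L,
                             gcContent = 0.42, nG4 = 60L, nHDNA = 40L,
                             nSTR = 10L, strUnit = "GAA", strCopies = 10L,
                             nGenes = 600L, nPeaks = 300L,
                             fracMotifPeaks = 0.5, baseHeight = 500,
                             foldChange = 2, relativeRisk = 3,
                             depth = 50000L, readLength = 75L,
                             spikeCellRatio = 4.2,
                             spikeGenomeLength = 50000L,
                             rnaseHAttenuation = 8, seed = 1L) {
  new("SimulationConfig", genomeLength = as.integer(genomeLength),
      nChroms = as.integer(nChroms), gcContent = gcContent,
      nG4 = as.integer(nG4), nHDNA = as.integer(nHDNA),
      nSTR = as.integer(nSTR), strUnit = toupper(strUnit),
      strCopies = as.integer(strCopies), nGenes = as.integer(nGenes),
      nPeaks = as.integer(nPeaks), fracMotifPeaks = fracMotifPeaks,
      baseHeight = baseHeight, foldChange = foldChange,
      relativeRisk = relativeRisk, depth = as.integer(depth),
      readLength = as.integer(readLength), spikeCellRatio = spikeCellRatio,
      spikeGenomeLength = as.integer(spikeGenomeLength),
      rnaseHAttenuation = rnaseHAttenuation, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@genomeLength, "bp /", object@nChroms,
      "chromosome(s),", object@nGenes, "genes,", object@nPeaks, "peaks\n")
  cat("  motifs planted: G4 =", object@nG4, " H-DNA =", object@nHDNA,
      " STR =", object@nSTR, paste0("(", object@strUnit, ")"), "\n")
  cat("  fold change", object@foldChange, "at motif peaks; spike ratio 1:",
      object@spikeCellRatio, "; RNase H attenuation ",
      object@rnaseHAttenuation, "x\n", sep = "")
})
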