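## Per-window signal profiles, spike-in / RNase H normalization, and a
## minimal peak caller for synthetic end-to-end runs.

#' Count reads in fixed-width windows
#'
#' Builds a raw [WindowProfile-class] from aligned-read intervals: each
#' read increments exactly one window, the one containing its start
#' coordinate, so counts are conserved (the sum over windows equals the
#' number of reads).
#'
#' @param reads a [GenomicRanges::GRanges] of read intervals (1-based,
#'   closed, the GRanges convention).
#' @param chromSizes named numeric/integer vector of chromosome lengths in
#'   bp.
#' @param width window width in bp (default 100).
#' @param sampleId optional label stored in the profile.
#' @return a raw (unnormalized) [WindowProfile-class].
#' @examples
#' reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 96), width = 75))
#' windowCounts(reads, c(chr1 = 1000))
#' @seealso [normalizeProfile()], [callPeaksSimple()]
#' @export
windowCounts <- function(reads, chromSizes, width = 100L,
                         sampleId = NA_character_) {
  stopifnot(is(reads, "GRanges"), width >= 1L)
  chromSizes <- setNames(as.integer(chromSizes), names(chromSizes))
  if (is.null(names(chromSizes)) || any(!nzchar(names(chromSizes))))
    stop("chromSizes must be a named vector")
  chr <- as.character(seqnames(reads))
  unknown <- setdiff(unique(chr), names(chromSizes))
  if (length(unknown))
    stop("reads on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (length(reads) && (any(start(reads) < 1L) ||
      any(start(reads) > chromSizes[chr])))
    stop("read start coordinates outside chromosome bounds")
  nwin <- ceiling(chromSizes / width)
  vals <- lapply(names(chromSizes), function(cn) {
    idx <- (start(reads)[chr == cn] - 1L) %/% as.integer(width) + 1L
    as.numeric(tabulate(idx, nbins = nwin[[cn]]))
  })
  new("WindowProfile", values = setNames(vals, names(chromSizes)),
      windowWidth = as.integer(width), chromSizes = chromSizes,
      normalized = FALSE, normFactor = 1, sampleId = as.character(sampleId))
}

#' Spike-in normalize a window profile
#'
#' Applies the three-step normalization used for display profiles: each
#' window count `c` becomes
#' `(c / T) * (spikeReference / (s / T)) * yieldFactor`,
#' i.e. depth normalization by the library's uniquely mapped
#' experimental-genome reads `T`, rescaling by the relative abundance of
#' the spike genome (`s / T`, the fraction of reads mapping to the spike)
#' against a batch reference, and the RNase H yield correction.
#' Algebraically the first two steps collapse to `c * spikeReference / s`,
#' so a library's sequencing depth cancels exactly: both `c` and `s` scale
#' with depth, and only the spike-anchored per-cell signal remains.
#'
#' `spikeReference` is the batch-level reference spike fraction
#' (conventionally the mean of `s/T` across the batch, see
#' [batchSpikeFraction()]); any constant rescales all samples jointly, so
#' between-sample ratios do not depend on it.  `yieldFactor` is the
#' relative nucleic-acid recovery (1 for untreated; 1/8 by default for
#' RNase H-treated samples, which recover at least eightfold less
#' material).  RNase H degrades spike and experimental hybrids alike, so
#' the read composition cannot see the global loss; multiplying by the
#' measured relative recovery restores absolute comparability, and the
#' RNase H-resistant residual signal displays low, as a specificity
#' control should.
#'
#' @param profile a raw [WindowProfile-class].
#' @param lib the matching [SpikeInLibrary-class].
#' @param spikeReference positive batch reference spike fraction.
#' @return the normalized [WindowProfile-class]; normalizing twice is an
#'   error.
#' @examples
#' wp <- windowCounts(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 75)),
#'                    c(chr1 = 1000))
#' lib <- SpikeInLibrary("s1", readsExperimental = 1e6, readsSpike = 2e5)
#' normalizeProfile(wp, lib, spikeReference = 0.1)
#' @export
normalizeProfile <- function(profile, lib, spikeReference) {
  stopifnot(is(profile, "WindowProfile"), is(lib, "SpikeInLibrary"))
  if (isNormalized(profile))
    stop("profile is already normalized; refusing to normalize twice")
  if (spikeReads(lib) <= 0)
    stop("library '", sampleId(lib), "' has zero spike reads")
  if (experimentalReads(lib) <= 0)
    stop("library '", sampleId(lib), "' has zero experimental reads")
  if (spikeReference <= 0) stop("spikeReference must be > 0")
  f <- (1 / experimentalReads(lib)) *
    (spikeReference / (spikeReads(lib) / experimentalReads(lib))) *
    yieldFactor(lib)
  initialize(profile, values = lapply(profile@values, `*`, f),
             normalized = TRUE, normFactor = f, sampleId = sampleId(lib))
}

#' Batch spike references
#'
#' `batchSpikeFraction`: mean spike-read fraction (`s/T`) across a set of
#' libraries, the reference for [normalizeProfile()].
#' `batchSpikeReads`: mean spike read count, the reference for
#' [normalizePeakHeights()].
#'
#' @param libs list of [SpikeInLibrary-class] objects.
#' @return a single numeric reference.
#' @export
batchSpikeFraction <- function(libs) {
  mean(vapply(libs, function(l) spikeReads(l) / experimentalReads(l),
              numeric(1)))
}

#' @rdname batchSpikeFraction
#' @export
batchSpikeReads <- function(libs) {
  mean(vapply(libs, spikeReads, numeric(1)))
}

#' Call peaks on a normalized window profile
#'
#' A deliberately simple threshold caller for synthetic end-to-end runs
#' (real-data peaks are expected to come from a dedicated caller such as
#' MACS2 and be ingested as BED).  Candidate peaks are maximal runs of at
#' least `minWindows` consecutive windows whose value is at least `fold`
#' times the median of the nonzero windows; candidate runs separated by at
#' most `mergeGap` bp are merged.  `rawHeight` is the maximum window value
#' within the peak expressed in raw read counts (the profile's linear
#' normalization factor is undone), so that [normalizePeakHeights()]
#' applies the spike correction exactly once.
#'
#' @param profile a normalized [WindowProfile-class].
#' @param fold threshold as a multiple of the nonzero-window median
#'   (default 5).
#' @param minWindows minimum run length in windows (default 2).
#' @param mergeGap maximum gap merged, in bp (default 200).
#' @return a [GenomicRanges::GRanges] of peaks with metadata columns
#'   `rawHeight`, `normHeight` (`NA` until [normalizePeakHeights()]) and
#'   `sampleId`; empty for an all-zero profile.
#' @export
callPeaksSimple <- function(profile, fold = 5, minWindows = 2L,
                            mergeGap = 200L) {
  stopifnot(is(profile, "WindowProfile"))
  if (!isNormalized(profile))
    stop("call peaks on a normalized profile (see normalizeProfile)")
  allv <- unlist(profile@values, use.names = FALSE)
  nz <- allv[allv > 0]
  if (!length(nz)) return(.emptyPeaks())
  thr <- fold * median(nz)
  w <- windowWidth(profile)
  out <- lapply(names(profile@values), function(cn) {
    v <- profile@values[[cn]]
    r <- rle(v >= thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minWindows
    if (!any(keep)) return(NULL)
    runs <- cbind(starts[keep], ends[keep])       # window indices, 1-based
    ## merge runs whose bp gap is <= mergeGap
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1L) for (i in 2:nrow(runs)) {
      gapBp <- (runs[i, 1] - merged[nrow(merged), 2] - 1L) * w
      if (gapBp <= mergeGap) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    gr <- GRanges(cn, IRanges((merged[, 1] - 1L) * w + 1L,
                              pmin(merged[, 2] * w,
                                   profile@chromSizes[[cn]])))
    mcols(gr)$rawHeight <- vapply(seq_len(nrow(merged)), function(i)
      max(v[merged[i, 1]:merged[i, 2]]), numeric(1)) / profile@normFactor
    gr
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(.emptyPeaks())
  gr <- sort(suppressWarnings(do.call(c, out)), ignore.strand = TRUE)
  mcols(gr)$normHeight <- NA_real_
  mcols(gr)$sampleId <- profile@sampleId
  gr
}

.emptyPeaks <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(rawHeight = numeric(0), normHeight = numeric(0),
                         sampleId = character(0))
  gr
}

#' Spike-normalize peak heights
#'
#' Scales each peak's raw height by `spikeReference / s`, the library's
#' spike-read correction, so heights are comparable across libraries of
#' different depth.  Order and coordinates are preserved.
#'
#' @param peaks a peak [GenomicRanges::GRanges] with a `rawHeight` column
#'   (from [callPeaksSimple()] or [readPeaksBed()]).
#' @inheritParams normalizeProfile
#' @return the same GRanges with `normHeight` filled in.
#' @export
normalizePeakHeights <- function(peaks, lib, spikeReference) {
  stopifnot(is(peaks, "GRanges"), is(lib, "SpikeInLibrary"))
  if (spikeReads(lib) <= 0)
    stop("library '", sampleId(lib), "' has zero spike reads")
  if (spikeReference <= 0) stop("spikeReference must be > 0")
  if (!"rawHeight" %in% colnames(mcols(peaks)))
    stop("peaks must carry a rawHeight metadata column")
  mcols(peaks)$normHeight <- mcols(peaks)$rawHeight *
    spikeReference / spikeReads(lib)
  mcols(peaks)$sampleId <- rep(sampleId(lib), length(peaks))
  peaks
}

#' @describeIn windowCounts convert a profile to a GRanges (one range per
#'   window, value in the `score` column), e.g. for bedGraph export.
#' @param x a [WindowProfile-class].
#' @export
profileGRanges <- function(x) {
  stopifnot(is(x, "WindowProfile"))
  w <- windowWidth(x)
  grl <- lapply(names(x@values), function(cn) {
    v <- x@values[[cn]]
    n <- length(v)
    GRanges(cn, IRanges((seq_len(n) - 1L) * w + 1L,
                        pmin(seq_len(n) * w, x@chromSizes[[cn]])),
            score = v)
  })
  gr <- do.call(c, grl)
  seqlengths(gr) <- x@chromSizes[seqlevels(gr)]
  gr
}
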