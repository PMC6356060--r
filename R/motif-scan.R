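## Motif scanning: G4 motifs, H-DNA (triplex) mirror repeats, and short
## tandem repeats.  All scanners take a DNAStringSet (or named character
## vector), work case-insensitively, treat N as matching no motif symbol,
## and return hits as a GRanges with metadata columns motifClass, score and
## unit, sorted by (chrom, start).

## G4 regex components for a given parameterisation; loops are [ACGT] so
## that an N inside a candidate disqualifies the match
.g4Pattern <- function(gMin, gMax, loopMin, loopMax) {
  sprintf("G{%d,%d}(?:[ACGT]{%d,%d}G{%d,%d}){3}",
          gMin, gMax, loopMin, loopMax, gMin, gMax)
}

## leftmost-then-longest, non-overlapping matches of the G4 pattern on one
## strand of one sequence; returns 0-based half-open starts/ends
.g4ScanStrand <- function(seq, gMin, gMax, loopMin, loopMax) {
  pat <- .g4Pattern(gMin, gMax, loopMin, loopMax)
  anchored <- paste0("^(?:", pat, ")$")
  lmax <- 4L * gMax + 3L * loopMax
  lmin <- 4L * gMin + 3L * loopMin
  starts <- integer(0); ends <- integer(0)
  offset <- 0L                       # 0-based offset of `rest` within seq
  rest <- seq
  repeat {
    m <- regexpr(pat, rest, perl = TRUE)
    if (m == -1L) break
    i <- as.integer(m)               # 1-based within rest; leftmost start
    hi <- min(lmax, nchar(rest) - i + 1L)
    len <- 0L
    for (L in seq.int(hi, lmin, by = -1L)) {  # longest match at leftmost start
      if (grepl(anchored, substr(rest, i, i + L - 1L), perl = TRUE)) {
        len <- L
        break
      }
    }
    ## regexpr matched, so some length in [lmin, hi] must match
    stopifnot(len > 0L)
    starts <- c(starts, offset + i - 1L)
    ends <- c(ends, offset + i - 1L + len)
    offset <- offset + i - 1L + len
    rest <- substr(rest, i + len, nchar(rest))
    if (!nzchar(rest)) break
  }
  list(start = starts, end = ends)
}

#' Scan for G-quadruplex motifs
#'
#' Finds matches of the canonical G4 consensus -- four runs of `gMin` to
#' `gMax` guanines separated by three loops of `loopMin` to `loopMax`
#' arbitrary bases (default `G3-5 N1-7 G3-5 N1-7 G3-5 N1-7 G3-5`).  Matches
#' are non-overlapping and leftmost-first; at each leftmost feasible start
#' the longest matching substring is taken.  With `bothStrands` the reverse
#' complement is scanned too and hits are mapped back to forward
#' coordinates with strand `-` (a `-` hit is a run of C-tracts on the
#' forward sequence).  `N` never matches any motif symbol, so a candidate
#' containing `N` is disqualified.
#'
#' @param subject a [Biostrings::DNAStringSet] or named character vector of
#'   sequences over A, C, G, T, N (case-insensitive).
#' @param gMin,gMax G-run length bounds (defaults 3 and 5).
#' @param loopMin,loopMax loop length bounds (defaults 1 and 7).
#' @param bothStrands scan the reverse complement as well (default `TRUE`).
#' @return a [GenomicRanges::GRanges] of hits with metadata columns
#'   `motifClass` (`"G4"`), `score` (number of G-tracts times the minimum
#'   tract length, a class-level stability proxy) and `unit` (`""`),
#'   sorted by (chrom, start).
#' @examples
#' scanG4(c(chr1 = "GGGTGGGTGGGTGGG"))
#' scanG4(c(chr1 = "CCCTCCCTCCCTCCC"))  # minus-strand hit
#' @seealso [scanHDNA()], [scanSTR()], [writeMotifBed()]
#' @export
scanG4 <- function(subject, gMin = 3L, gMax = 5L, loopMin = 1L,
                   loopMax = 7L, bothStrands = TRUE) {
  stopifnot(gMin >= 1L, gMax >= gMin, loopMin >= 1L, loopMax >= loopMin)
  seqs <- .asSeqSet(subject)
  hits <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    n <- nchar(s)
    fwd <- .g4ScanStrand(s, gMin, gMax, loopMin, loopMax)
    out <- .hitsGRanges(nm, fwd$start, fwd$end, "+", "G4", 4 * gMin)
    if (bothStrands && n > 0L) {
      rc <- as.character(reverseComplement(DNAString(s)))
      rev <- .g4ScanStrand(rc, gMin, gMax, loopMin, loopMax)
      out <- c(out, .hitsGRanges(nm, n - rev$end, n - rev$start, "-",
                                 "G4", 4 * gMin))
    }
    out
  })
  .combineHits(hits)
}

## mismatch penalty per mirror-arm mismatch; > 2 guarantees a candidate
## whose outermost pair mismatches always scores below its trimmed version
.HDNA_MISMATCH_PENALTY <- 3

#' Scan for H-DNA (intramolecular triplex) candidate motifs
#'
#' Detects mirror repeats with homopurine/homopyrimidine character, the
#' sequence signature of H-DNA-forming tracts such as (GAA)n.  A candidate
#' is a pair of arms of equal length `>= minArm` separated by a spacer of
#' at most `maxSpacer` bp, where the second arm equals the reverse (not
#' reverse complement) of the first up to `maxMismatch` mismatches, and the
#' combined arms are at least `minPurity` purine or at least `minPurity`
#' pyrimidine.  Candidate score is `2*armLength - 3*mismatches`; from all
#' candidates, a maximal non-overlapping subset is selected greedily by
#' decreasing score (ties to the leftmost, then shortest).  This is a
#' deliberately transparent approximation of model-based triplex scoring;
#' all thresholds are exposed.  Hits are strand-symmetric and reported on
#' `+`.
#'
#' @inheritParams scanG4
#' @param minArm minimum arm length in bp (default 6).
#' @param maxSpacer maximum spacer between the arms in bp (default 8).
#' @param maxMismatch maximum arm mismatches tolerated (default 1).
#' @param minPurity minimum purine (or pyrimidine) fraction of the combined
#'   arms (default 0.9).
#' @param maxArm maximum arm length searched (default 25).
#' @return a [GenomicRanges::GRanges] of hits (`motifClass = "HDNA"`).
#' @examples
#' scanHDNA(c(chr1 = paste0("GGAAGGAAG", "TTTT", "GAAGGAAGG")))
#' @export
scanHDNA <- function(subject, minArm = 6L, maxSpacer = 8L, maxMismatch = 1L,
                     minPurity = 0.9, maxArm = 25L) {
  stopifnot(minArm >= 4L, maxSpacer >= 0L, maxMismatch >= 0L,
            minPurity >= 0, minPurity <= 1, maxArm >= minArm)
  seqs <- .asSeqSet(subject)
  hits <- lapply(names(seqs), function(nm) {
    cand <- .hdnaCandidates(seqs[[nm]], minArm, maxSpacer, maxMismatch,
                            minPurity, maxArm)
    sel <- .selectNonOverlapping(cand)
    .hitsGRanges(nm, sel$start, sel$end, "+", "HDNA", sel$score)
  })
  .combineHits(hits)
}

## enumerate all (arm end, spacer, arm length) candidates, vectorised over
## arm-end positions; returns a data.frame of 0-based half-open intervals
.hdnaCandidates <- function(seq, minArm, maxSpacer, maxMismatch, minPurity,
                            maxArm) {
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0))
  if (n < 2L * minArm) return(empty)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  isN <- ch == "N"
  cumPur <- cumsum(ch %in% c("A", "G"))
  cumPyr <- cumsum(ch %in% c("C", "T"))
  cumN <- cumsum(isN)
  at <- function(cum, i) {
    v <- cum[pmin(pmax(i, 1L), n)]
    v[i < 1L] <- 0
    v
  }
  out <- vector("list", maxSpacer + 1L)
  for (d in 0:maxSpacer) {
    ## e1 = 1-based position of the last base of arm1
    e1 <- seq_len(n)
    mism <- numeric(n)
    rows <- vector("list", maxArm)
    for (k in seq_len(maxArm)) {
      ## pair t = k-1: arm1 base e1-k+1 vs arm2 base e1+d+k
      i1 <- e1 - k + 1L
      i2 <- e1 + d + k
      ok <- i1 >= 1L & i2 <= n
      eq <- rep(FALSE, n)
      eq[ok] <- ch[i1[ok]] == ch[i2[ok]] & !isN[i1[ok]] & !isN[i2[ok]]
      mism <- mism + as.numeric(!eq)
      if (k < minArm) next
      ## candidate arms [e1-k+1, e1] and [e1+d+1, e1+d+k]
      purArms <- (at(cumPur, e1) - at(cumPur, e1 - k)) +
                 (at(cumPur, e1 + d + k) - at(cumPur, e1 + d))
      pyrArms <- (at(cumPyr, e1) - at(cumPyr, e1 - k)) +
                 (at(cumPyr, e1 + d + k) - at(cumPyr, e1 + d))
      nAny <- at(cumN, e1 + d + k) - at(cumN, e1 - k)
      keep <- ok & mism <= maxMismatch & nAny == 0 &
        (purArms + 1e-9 >= minPurity * 2 * k |
         pyrArms + 1e-9 >= minPurity * 2 * k)
      if (!any(keep)) next
      rows[[k]] <- data.frame(
        start = e1[keep] - k,               # 0-based
        end = e1[keep] + d + k,
        score = 2 * k - .HDNA_MISMATCH_PENALTY * mism[keep])
    }
    out[[d + 1L]] <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) empty else res
}

## greedy non-overlap selection: best score first, ties leftmost then
## shortest; shared with the brute-force oracle contract
.selectNonOverlapping <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  ord <- order(-cand$score, cand$start, cand$end)
  cand <- cand[ord, , drop = FALSE]
  maxEnd <- max(cand$end)
  covered <- logical(maxEnd)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):cand$end[i]
    if (!any(covered[span])) {
      covered[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  res <- cand[keep, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

#' Scan for perfect short tandem repeat arrays
#'
#' Finds maximal perfect tandem arrays of `unit` with at least `minCopies`
#' copies, e.g. the engineered (GAA)n tracts used as replication
#' impediments.  Partial trailing copies are excluded; the score is the
#' full copy number.
#'
#' @inheritParams scanG4
#' @param unit repeat unit (e.g. `"GAA"`), over A/C/G/T.
#' @param minCopies minimum number of full copies (default 4, must be >= 2).
#' @return a [GenomicRanges::GRanges] of hits (`motifClass = "STR"`,
#'   `unit` = the repeat unit, `score` = copy number), strand `+`.
#' @examples
#' scanSTR(c(chr1 = strrep("GAA", 10)), "GAA", minCopies = 4)
#' @export
scanSTR <- function(subject, unit, minCopies = 4L) {
  unit <- .checkSeq(unit, "unit")
  if (grepl("N", unit, fixed = TRUE) || !nzchar(unit))
    stop("unit must be a nonempty string over A/C/G/T")
  stopifnot(minCopies >= 2L)
  seqs <- .asSeqSet(subject)
  pat <- sprintf("(?:%s){%d,}", unit, as.integer(minCopies))
  hits <- lapply(names(seqs), function(nm) {
    m <- gregexpr(pat, seqs[[nm]], perl = TRUE)[[1]]
    if (m[1] == -1L) return(.emptyHits())
    st <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    .hitsGRanges(nm, st, st + len, "+", "STR", len / nchar(unit), unit)
  })
  .combineHits(hits)
}
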