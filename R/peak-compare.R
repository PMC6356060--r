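## Two-condition peak comparison: one-to-one peak matching, shared
## fractions, Mann-Whitney height comparison, and height regression.

#' Match peaks between two conditions
#'
#' One-to-one matching of two peak sets, following the boundary rules used
#' for genome-wide peak comparisons: in `overlap` mode two peaks match if
#' they share at least 1 bp; in `proximity` mode peaks separated by a gap
#' of at most `maxGap` bp (default 1000) also match.  Candidate pairs are
#' assigned greedily by increasing gap (then decreasing overlap, then
#' leftmost), so each peak participates in at most one match.  Shared
#' fractions are reported relative to set A, set B, and the union of both
#' sets.
#'
#' @param setA,setB peak [GenomicRanges::GRanges] (internally
#'   non-overlapping; overlapping peaks within a set are merged with a
#'   warning, keeping the maximum height).
#' @param mode `"overlap"` or `"proximity"`.
#' @param maxGap maximum gap in bp for proximity matching (default 1000).
#' @return a list with `matches` (data.frame: `indexA`, `indexB`,
#'   `overlapBp`, `gapBp`, and `heightA`/`heightB` when the inputs carry
#'   `normHeight`), `sharedFractionA`, `sharedFractionB` and
#'   `sharedFractionUnion`.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
#' matchPeaks(a, b)$matches                      # 1 bp overlap
#' @export
matchPeaks <- function(setA, setB, mode = c("overlap", "proximity"),
                       maxGap = 1000L) {
  mode <- match.arg(mode)
  setA <- .tidyPeakSet(setA, "setA")
  setB <- .tidyPeakSet(setB, "setB")
  nA <- length(setA); nB <- length(setB)
  matches <- data.frame(indexA = integer(0), indexB = integer(0),
                        overlapBp = integer(0), gapBp = integer(0))
  if (nA && nB) {
    gap <- if (mode == "proximity") as.integer(maxGap) else -1L
    ## candidate pairs: >=1 bp overlap always; within maxGap in proximity
    ## mode (findOverlaps maxgap counts adjacent ranges as gap 0)
    hi <- findOverlaps(setA, setB, maxgap = gap)
    if (length(hi)) {
      qa <- queryHits(hi); sb <- subjectHits(hi)
      ov <- pmax(0L, pmin(end(setA)[qa], end(setB)[sb]) -
                       pmax(start(setA)[qa], start(setB)[sb]) + 1L)
      gp <- ifelse(ov > 0L, 0L,
                   pmax(start(setA)[qa], start(setB)[sb]) -
                   pmin(end(setA)[qa], end(setB)[sb]) - 1L)
      keep <- ov > 0L | (mode == "proximity" & gp <= maxGap)
      qa <- qa[keep]; sb <- sb[keep]; ov <- ov[keep]; gp <- gp[keep]
      ord <- order(gp, -ov, start(setA)[qa], start(setB)[sb])
      usedA <- logical(nA); usedB <- logical(nB)
      sel <- logical(length(ord))
      for (i in ord) {
        if (!usedA[qa[i]] && !usedB[sb[i]]) {
          usedA[qa[i]] <- TRUE; usedB[sb[i]] <- TRUE
          sel[i] <- TRUE
        }
      }
      matches <- data.frame(indexA = qa[sel], indexB = sb[sel],
                            overlapBp = ov[sel], gapBp = gp[sel])
      matches <- matches[order(matches$indexA), , drop = FALSE]
      rownames(matches) <- NULL
    }
  }
  if ("normHeight" %in% colnames(mcols(setA)) &&
      "normHeight" %in% colnames(mcols(setB))) {
    matches$heightA <- mcols(setA)$normHeight[matches$indexA]
    matches$heightB <- mcols(setB)$normHeight[matches$indexB]
  }
  list(matches = matches,
       sharedFractionA = if (nA) nrow(matches) / nA else 0,
       sharedFractionB = if (nB) nrow(matches) / nB else 0,
       sharedFractionUnion = if (nA + nB) 2 * nrow(matches) / (nA + nB)
                             else 0)
}

## sort a peak set; merge any internal overlaps (max height kept)
.tidyPeakSet <- function(gr, what) {
  stopifnot(is(gr, "GRanges"))
  if (is.unsorted(order(as.character(seqnames(gr)), start(gr))))
    gr <- sort(gr, ignore.strand = TRUE)
  ## min.gapwidth = 0: merge true overlaps only, never adjacent peaks
  red <- reduce(gr, ignore.strand = TRUE, min.gapwidth = 0L)
  if (length(red) < length(gr)) {
    warning(what, " contains internally overlapping peaks; merged")
    if ("normHeight" %in% colnames(mcols(gr))) {
      hi <- findOverlaps(red, gr)
      mcols(red)$normHeight <- vapply(seq_along(red), function(i)
        max(mcols(gr)$normHeight[subjectHits(hi)[queryHits(hi) == i]]),
        numeric(1))
    }
    gr <- red
  }
  gr
}

#' Mann-Whitney U test for peak-height comparisons
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test.  For small samples
#' (`nA + nB <= exactLimit`, default 16) the p-value is exact by complete
#' enumeration of group labelings, handling ties; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#' `U` is the number of (a, b) pairs with `a > b`, counting ties 1/2.
#'
#' @param heightsA,heightsB numeric vectors (each nonempty).
#' @param exactLimit maximum total sample size for the exact enumeration.
#' @return an object of class `"HeightComparison"`: list with
#'   `uStatistic`, `pValue`, `nA`, `nB`, `exact`, and a `summary`
#'   data.frame of per-group median, interquartile range and lower/upper
#'   inner fences (quartile -/+ 1.5 IQR), the statistics drawn in the
#'   standard violin summaries.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))   # exact two-sided p = 2/6
#' @export
mannWhitney <- function(heightsA, heightsB, exactLimit = 16L) {
  heightsA <- as.numeric(heightsA); heightsB <- as.numeric(heightsB)
  if (!length(heightsA) || !length(heightsB))
    stop("both groups must be nonempty")
  if (anyNA(heightsA) || anyNA(heightsB)) stop("heights must not contain NA")
  nA <- length(heightsA); nB <- length(heightsB); n <- nA + nB
  pool <- c(heightsA, heightsB)
  r <- rank(pool)
  u <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  exact <- n <= exactLimit
  if (exact) {
    ## complete enumeration of which pooled elements form group A
    idx <- combn(n, nA)
    uDist <- colSums(matrix(r[idx], nrow = nA)) - nA * (nA + 1) / 2
    p <- mean(abs(uDist - mu) >= abs(u - mu) - 1e-9)
  } else {
    tie <- table(r)
    sigma <- sqrt(nA * nB / 12 *
                  ((n + 1) - sum(tie^3 - tie) / (n * (n - 1))))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- sign(z) * max(0, abs(z) - 0.5)     # continuity correction
      p <- min(1, 2 * pnorm(abs(z) / sigma, lower.tail = FALSE))
    }
  }
  summ <- do.call(rbind, lapply(list(A = heightsA, B = heightsB), function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               iqr = iqr, lowerFence = q[1] - 1.5 * iqr,
               upperFence = q[3] + 1.5 * iqr)
  }))
  structure(list(uStatistic = u, pValue = p, nA = nA, nB = nB,
                 exact = exact, summary = summ),
            class = "HeightComparison")
}

#' @export
print.HeightComparison <- function(x, ...) {
  cat("Mann-Whitney U comparison (", if (x$exact) "exact" else
      "normal approximation, tie-corrected", ")\n", sep = "")
  cat("  U =", x$uStatistic, " nA =", x$nA, " nB =", x$nB,
      " two-sided p =", format.pval(x$pValue, digits = 4), "\n")
  print(x$summary)
  invisible(x)
}

#' Regress matched peak heights between conditions
#'
#' Ordinary least-squares fit of condition-B heights on condition-A
#' heights over matched peaks, by default on the log10 scale (so a uniform
#' k-fold height change appears as intercept log10(k) with slope 1, and
#' the fit can be drawn against the 1:1 line).
#'
#' @param matches the `matches` data.frame from [matchPeaks()] (must carry
#'   `heightA`/`heightB`), or a data.frame with those two columns.
#' @param log10Scale fit on log10-transformed heights (default `TRUE`;
#'   requires positive heights).
#' @return list with `slope`, `intercept`, `r` (Pearson correlation on the
#'   fitted scale) and `n`.
#' @export
regressHeights <- function(matches, log10Scale = TRUE) {
  if (!all(c("heightA", "heightB") %in% names(matches)))
    stop("matches must carry heightA and heightB columns")
  x <- matches$heightA; y <- matches$heightB
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 matched peaks")
  if (log10Scale) {
    if (any(x <= 0) || any(y <= 0))
      stop("log10 regression requires positive heights")
    x <- log10(x); y <- log10(y)
  }
  if (sd(x) == 0) stop("heightA is constant; regression is degenerate")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(x, y), n = length(x))
}
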