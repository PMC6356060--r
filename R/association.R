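## Gene association statistics: gene-overlap fractions, hypergeometric
## enrichment of motif-bearing genes among peak-bearing genes, and
## metagene peak distributions.

#' Genes overlapping (or near) a feature set
#'
#' Returns the genes touched by at least one feature, using the same
#' >= 1 bp overlap rule as peak matching; with `maxGap > 0` features
#' within `maxGap` bp of a gene also count (the 1-kb proximity rule used
#' for extragenic analyses).  Swapping the roles of the arguments gives
#' the extragenic view (e.g. non-genic peaks near motifs).
#'
#' @param genes a [GenomicRanges::GRanges] of gene models with a `gene_id`
#'   metadata column (or unnamed; indices are used as ids).
#' @param features a [GenomicRanges::GRanges] of motifs or peaks.
#' @param maxGap proximity allowance in bp (default 0 = overlap only).
#' @return list with `geneIds` (character), `n` (genes hit), `total` and
#'   `fraction`.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
#'                             gene_id = "g1")
#' m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 510))
#' genesWithFeature(g, m)$fraction
#' @seealso [hypergeomEnrichment()], [metageneDistribution()]
#' @export
genesWithFeature <- function(genes, features, maxGap = 0L) {
  stopifnot(is(genes, "GRanges"), is(features, "GRanges"), maxGap >= 0L)
  ids <- .geneIds(genes)
  hit <- countOverlaps(genes, features, ignore.strand = TRUE,
                       maxgap = if (maxGap > 0L) as.integer(maxGap)
                                else -1L) > 0L
  list(geneIds = ids[hit], n = sum(hit), total = length(genes),
       fraction = if (length(genes)) sum(hit) / length(genes) else 0)
}

.geneIds <- function(genes) {
  if ("gene_id" %in% colnames(mcols(genes)))
    as.character(mcols(genes)$gene_id)
  else as.character(seq_along(genes))
}

#' Upper-tail hypergeometric enrichment test
#'
#' Tests whether genes overlapping peaks are enriched for genes
#' overlapping motifs: from `N` genes of which `K` carry a motif, `n`
#' peak-bearing genes are "drawn" and `k` carry both.  Returns
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, evaluated with
#' [stats::phyper()] (log-space internally, numerically stable).
#'
#' @param N total genes; `K` motif-bearing genes; `n` peak-bearing genes;
#'   `k` genes with both.
#' @param K,n,k see `N`.
#' @return list with `pValue`, the fold enrichment
#'   `(k/n) / (K/N)`, and the input table.
#' @examples
#' hypergeomEnrichment(10, 5, 5, 5)$pValue * 252   # = 1
#' @export
hypergeomEnrichment <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n) ||
      k < max(0, n - (N - K)))
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N and ",
         "k >= max(0, n - (N - K))")
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  list(pValue = p, foldEnrichment = fold,
       table = data.frame(N = N, K = K, n = n, k = k))
}

#' Build a gene/motif/peak enrichment table
#'
#' Convenience wrapper composing [genesWithFeature()] and
#' [hypergeomEnrichment()]: counts motif-bearing genes, peak-bearing
#' genes, and their intersection, then tests enrichment.
#'
#' @inheritParams genesWithFeature
#' @param motifs,peaks feature GRanges.
#' @return list with the counts (`N`, `K`, `n`, `k`), the two gene
#'   fractions (`fractionMotifGenes` = K/N, `fractionPeakGenesWithMotif` =
#'   k/n), `foldEnrichment` and `pValue`.
#' @export
enrichmentTable <- function(genes, motifs, peaks, maxGap = 0L) {
  gm <- genesWithFeature(genes, motifs, maxGap)
  gp <- genesWithFeature(genes, peaks, maxGap)
  k <- length(intersect(gm$geneIds, gp$geneIds))
  ht <- hypergeomEnrichment(length(genes), gm$n, gp$n, k)
  list(N = length(genes), K = gm$n, n = gp$n, k = k,
       fractionMotifGenes = gm$fraction,
       fractionPeakGenesWithMotif = if (gp$n) k / gp$n else NA_real_,
       foldEnrichment = ht$foldEnrichment, pValue = ht$pValue)
}

#' Metagene distribution of peaks over scaled gene bodies
#'
#' Assigns each peak's midpoint to one bin of a common scaled gene
#' coordinate: `flankBins` bins over the `flankBp` upstream flank, then
#' `bodyBins` bins over the gene body rescaled to 0--1, then `flankBins`
#' bins over the downstream flank.  Assignment is strand-aware (upstream
#' means 5' of the TSS).  Overlapping genes are flattened (merged) first;
#' a peak falling in several gene windows is assigned to the nearest gene
#' (leftmost on ties).  Fractions are relative to all peaks, so the
#' profile sums to the fraction of peaks within `flankBp` of any gene.
#' The same function profiles any feature set (e.g. motifs) as a
#' background track.
#'
#' @param peaks a [GenomicRanges::GRanges] of peaks (or any features).
#' @param genes a [GenomicRanges::GRanges] of gene models (strand used).
#' @param bodyBins bins over the gene body (default 40).
#' @param flankBp flank width in bp (default 2000).
#' @param flankBins bins per flank (default 20).
#' @return data.frame with `bin` (1..flankBins+bodyBins+flankBins),
#'   `region` (`"upstream"`, `"body"`, `"downstream"`), `position`
#'   (scaled coordinate, body = 0..1) and `fraction`.
#' @export
metageneDistribution <- function(peaks, genes, bodyBins = 40L,
                                 flankBp = 2000L, flankBins = 20L) {
  stopifnot(is(peaks, "GRanges"), is(genes, "GRanges"),
            bodyBins >= 1L, flankBins >= 1L, flankBp >= 1L)
  if (!length(genes)) stop("empty gene set")
  genes <- reduce(sort(genes), ignore.strand = FALSE)
  nBins <- 2L * flankBins + bodyBins
  counts <- numeric(nBins)
  nPeaks <- length(peaks)
  if (nPeaks) {
    mid <- (start(peaks) + end(peaks)) %/% 2L
    midGR <- GRanges(seqnames(peaks), IRanges(mid, mid))
    win <- GRanges(seqnames(genes),
                   IRanges(pmax(1L, start(genes) - flankBp),
                           end(genes) + flankBp))
    hi <- findOverlaps(midGR, win, ignore.strand = TRUE)
    if (length(hi)) {
      qh <- queryHits(hi); sh <- subjectHits(hi)
      ## nearest gene on multi-hits: distance to the gene body, leftmost tie
      d <- pmax(0L, pmax(start(genes)[sh] - mid[qh],
                         mid[qh] - end(genes)[sh]))
      ord <- order(qh, d, start(genes)[sh])
      first <- !duplicated(qh[ord])
      qh <- qh[ord][first]; sh <- sh[ord][first]
      gs <- start(genes)[sh]; ge <- end(genes)[sh]
      neg <- as.logical(strand(genes)[sh] == "-")
      m <- mid[qh]
      ## signed position: <0 upstream, [0,1] body, >1 downstream
      bodyLen <- ge - gs + 1L
      pos <- ifelse(m < gs, (m - gs) / flankBp,
             ifelse(m > ge, 1 + (m - ge) / flankBp,
                    (m - gs + 0.5) / bodyLen))
      pos[neg] <- ifelse(m[neg] > ge[neg], (ge[neg] - m[neg]) / flankBp,
                  ifelse(m[neg] < gs[neg],
                         1 + (gs[neg] - m[neg]) / flankBp,
                         (ge[neg] - m[neg] + 0.5) / bodyLen[neg]))
      bin <- ifelse(pos < 0,
                    flankBins + 1L + floor(pos * flankBins),
             ifelse(pos <= 1,
                    flankBins + pmin(bodyBins, floor(pos * bodyBins) + 1L),
                    flankBins + bodyBins +
                      pmin(flankBins, ceiling((pos - 1) * flankBins))))
      bin <- bin[bin >= 1L & bin <= nBins]
      tab <- tabulate(bin, nBins)
      counts <- counts + tab
    }
  }
  region <- rep(c("upstream", "body", "downstream"),
                c(flankBins, bodyBins, flankBins))
  position <- c(seq(-1, 0, length.out = flankBins + 1L)[-(flankBins + 1L)] +
                  0.5 / flankBins,
                (seq_len(bodyBins) - 0.5) / bodyBins,
                1 + (seq_len(flankBins) - 0.5) / flankBins)
  data.frame(bin = seq_len(nBins), region = region, position = position,
             fraction = if (nPeaks) counts / nPeaks else counts)
}
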