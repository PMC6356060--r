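# Small fixture builders shared across tests.

# random sequence with optional G enrichment so G4 scanners get real work
randomSeq <- function(n, gc = 0.45, gBias = 0) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2 + gBias,
         T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p / sum(p)),
        collapse = "")
}

# GRanges from a 2-column matrix/data.frame of 1-based closed intervals
grFrom <- function(df, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start, df$end))
}

# random non-overlapping intervals on one chromosome, 1-based closed
randomIntervals <- function(n, span = 100000, maxWidth = 400) {
  st <- sort(sample(span, n))
  wd <- sample(maxWidth, n, replace = TRUE)
  en <- st + wd - 1L
  keep <- c(TRUE, st[-1] > cummax(en)[-n])
  data.frame(start = st[keep], end = en[keep])
}

# a normalized WindowProfile built from crafted per-window read counts
profileFromCounts <- function(counts, width = 100L, chrom = "chr1",
                              Treads = NULL, s = 1000, ref = 1000) {
  starts <- rep((seq_along(counts) - 1L) * width + 1L, counts)
  reads <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(starts, width = 50L))
  wp <- windowCounts(reads, setNames(length(counts) * width, chrom),
                     width = width)
  lib <- SpikeInLibrary("fx", readsExperimental = if (is.null(Treads))
    max(1, sum(counts)) else Treads, readsSpike = s)
  normalizeProfile(wp, lib, ref)
}
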