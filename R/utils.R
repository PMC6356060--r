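## internal helpers shared across modules

## run `expr` under a temporary RNG state seeded with `seed`; restores the
## caller's .Random.seed so library code never clobbers user RNG streams
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## uppercase and validate a nucleotide string; N allowed, anything else fatal
.checkSeq <- function(seq, name = "sequence") {
  seq <- toupper(as.character(seq))
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    stop(sprintf("%s contains non-ACGTN characters: '%s'", name,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  }
  seq
}

## coerce character/DNAStringSet input to a named character vector of
## uppercase sequences
.asSeqSet <- function(x) {
  if (is(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x)) {
    seqs <- x
  } else {
    stop("sequences must be a DNAStringSet or named character vector")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence must have a nonempty name")
  vapply(seq_along(seqs), function(i)
    .checkSeq(seqs[[i]], names(seqs)[i]), character(1)) |>
    setNames(names(seqs))
}

## empty motif-hit GRanges with the standard metadata columns
.emptyHits <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(motifClass = character(0), score = numeric(0),
                         unit = character(0))
  gr
}

## build a motif-hit GRanges from 0-based half-open coordinates
.hitsGRanges <- function(chrom, start0, end0, strand, motifClass, score,
                         unit = "") {
  if (length(start0) == 0L) return(.emptyHits())
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  mcols(gr) <- DataFrame(motifClass = motifClass, score = score, unit = unit)
  gr
}

## combine per-chromosome hit sets and sort by (chrom, start) ignoring
## strand, the BED convention; combining GRanges with disjoint seqlevels
## triggers an informational Seqinfo warning that is irrelevant here
.combineHits <- function(hitsList) {
  gr <- suppressWarnings(do.call(c, c(hitsList, list(.emptyHits()))))
  sort(gr, ignore.strand = TRUE)
}
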