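## File-format adapters.  Standard formats (FASTA, BED, bedGraph) go
## through Biostrings/rtracklayer; the two bespoke tabular formats
## (BED6+1 peak files with a normalized-height column, and the YAML
## sample sheet) have small dedicated readers/writers.

#' Read and write two-column chrom.sizes files
#'
#' @param path file path.
#' @return `readChromSizes`: named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", col.names = c("chrom", "size"),
                   colClasses = c("character", "integer"))
  setNames(df$size, df$chrom)
}

#' @param chromSizes named vector of chromosome lengths.
#' @rdname readChromSizes
#' @export
writeChromSizes <- function(chromSizes, path) {
  write.table(data.frame(names(chromSizes), unname(chromSizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read aligned-read or feature intervals from BED
#'
#' Thin wrapper over [rtracklayer::import()] (0-based half-open BED is
#' converted to 1-based GRanges).
#'
#' @param path BED file path.
#' @return a [GenomicRanges::GRanges].
#' @export
readBedIntervals <- function(path) {
  import(path, format = "BED")
}

#' Write motif hits to BED6
#'
#' The name field is `motifClass` or `motifClass:unit` for tandem
#' repeats; the score field is the class-specific hit score.
#'
#' @param hits motif-hit GRanges from the scanners.
#' @param path output path.
#' @export
writeMotifBed <- function(hits, path) {
  unit <- if ("unit" %in% colnames(mcols(hits))) mcols(hits)$unit
          else rep("", length(hits))
  score <- if ("score" %in% colnames(mcols(hits))) mcols(hits)$score
           else rep(0, length(hits))
  nm <- ifelse(nzchar(unit), paste0(mcols(hits)$motifClass, ":", unit),
               mcols(hits)$motifClass)
  out <- hits
  mcols(out) <- DataFrame(name = nm, score = score)
  export(out, path, format = "BED")
  invisible(path)
}

#' Read and write peak files (BED6+1, extra normHeight column)
#'
#' Columns: chrom, start (0-based), end, name, rawHeight (score slot),
#' strand, normHeight.
#'
#' @param peaks peak GRanges with `rawHeight`/`normHeight` columns.
#' @param path file path.
#' @export
writePeaksBed <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = if (length(peaks))
                     paste0("peak", seq_along(peaks)) else character(0),
                   score = mcols(peaks)$rawHeight,
                   strand = ".",
                   normHeight = mcols(peaks)$normHeight)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writePeaksBed
#' @export
readPeaksBed <- function(path) {
  if (file.size(path) == 0) return(.emptyPeaks())
  df <- read.table(path, sep = "\t",
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand", "normHeight"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric", "character",
                                  "numeric"))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr) <- DataFrame(rawHeight = df$score, normHeight = df$normHeight,
                         sampleId = NA_character_)
  gr
}

#' Export a window profile as bedGraph
#'
#' Writes the per-window values (typically normalized signal) via
#' [rtracklayer::export()].
#'
#' @param profile a [WindowProfile-class].
#' @param path output path.
#' @export
writeProfileBedGraph <- function(profile, path) {
  export(profileGRanges(profile), path, format = "bedGraph")
  invisible(path)
}

#' Read and write YAML sample sheets
#'
#' One record per library with fields sampleId, condition, treatment,
#' T (experimental reads), s (spike reads), yieldFactor.
#'
#' @param sheet data.frame as produced by [simulateDripExperiment()].
#' @param path file path.
#' @export
writeSampleSheet <- function(sheet, path) {
  recs <- lapply(seq_len(nrow(sheet)), function(i) as.list(sheet[i, ]))
  write_yaml(list(libraries = recs), path)
  invisible(path)
}

#' @rdname writeSampleSheet
#' @return `readSampleSheet`: list with `sheet` (data.frame) and
#'   `libraries` (named list of [SpikeInLibrary-class]).
#' @export
readSampleSheet <- function(path) {
  recs <- read_yaml(path)$libraries
  sheet <- do.call(rbind, lapply(recs, function(r)
    data.frame(sampleId = r$sampleId, condition = r$condition,
               treatment = r$treatment, T = r$T, s = r$s,
               yieldFactor = r$yieldFactor)))
  libs <- lapply(recs, function(r)
    SpikeInLibrary(r$sampleId, r$condition, r$treatment,
                   readsExperimental = r$T, readsSpike = r$s,
                   yieldFactor = r$yieldFactor))
  names(libs) <- sheet$sampleId
  list(sheet = sheet, libraries = libs)
}

#' Read clone loss-fraction TSV files
#'
#' One file per cohort, as written by [simulateFluctuationCohorts()]:
#' columns `cloneId`, `lossFraction`, `nCellsSampled`.
#'
#' @param paths character vector of TSV paths; names become group names.
#' @return named list of numeric loss-fraction vectors, ready for
#'   [compareCohorts()].
#' @export
readFluctuationTsv <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.tsv$", "", basename(paths))
  lapply(setNames(paths, names(paths)), function(p)
    read.table(p, header = TRUE, sep = "\t")$lossFraction)
}
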