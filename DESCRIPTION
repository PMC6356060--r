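Package: structloop
Title: Quantitative Analysis of R-Loop Formation at Structure-Forming DNA Sequences
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying DNA:RNA hybrid (R-loop) immunoprecipitation
    sequencing signal at DNA secondary-structure-forming sequences.  Provides
    strand-aware scanners for G-quadruplex motifs (four G-run pattern),
    H-DNA/triplex candidate mirror repeats and short tandem repeats;
    spike-in-normalized per-window signal profiles with RNase H yield
    correction; a simple peak caller plus spike-normalized peak heights;
    two-condition peak matching and height comparison (exact and approximate
    Mann-Whitney U); gene-overlap and hypergeometric enrichment statistics and
    metagene peak distributions; a branching-process model of clonal
    epigenetic-switching fluctuation assays with switch-rate estimation; and a
    synthetic-data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
biocViews: Epigenetics, Sequencing, Coverage, PeakDetection, Transcription
Config/testthat/edition: 3
RoxygenNote: 7.3.3
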