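---
title: "Quantifying R-loop signal at structure-forming DNA: models and methods"
author: "structloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying R-loop signal at structure-forming DNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structloop)
library(GenomicRanges)
```

# The scientific question

R-loops are three-stranded structures formed during transcription: a
DNA:RNA hybrid plus a displaced single DNA strand.  Sequences that fold
into non-B DNA secondary structures -- G-quadruplexes (G4), H-DNA
triplexes at mirror-repeat homopurine tracts, and short (GAA)n tandem
repeats -- can stall replication forks and, when repriming downstream of
the block fails (for example in cells lacking the primase-polymerase
PrimPol), leave single-stranded gaps that favour R-loop formation and
epigenetically destabilise nearby genes.

Testing that idea genome-wide requires a quantitative chain:
locate candidate structure-forming sequences; measure DRIP-seq (or RNA
DIP-seq) signal in a way that is comparable *between* samples; decide
which peaks are shared between wild-type and mutant conditions and
whether their heights differ; relate peaks and motifs to genes with an
enrichment statistic; and model the clonal fluctuation assay that turns
loss-variant fractions into a per-division switching probability.
`structloop` implements that chain end to end, together with a
synthetic-data generator whose ground truth exercises every step.

# Motif scanning

## G4 motifs

`scanG4()` matches the canonical four-G-run consensus
`G3-5 N1-7 G3-5 N1-7 G3-5 N1-7 G3-5`: four runs of `gMin`--`gMax`
guanines (default 3--5) separated by three loops of `loopMin`--`loopMax`
arbitrary bases (default 1--7).  The consensus alone does not define a
match *policy*, so we fix one: matches are non-overlapping and
leftmost-first, and at each leftmost feasible start the longest matching
substring is taken.  Leftmost-longest is deterministic, independent of
regex-engine backtracking order, and easy to reproduce with a
brute-force enumerator -- which the test suite does on random sequences.
Both strands are scanned by default (DRIP signal is not
strand-resolved), with reverse-complement hits mapped back to forward
coordinates as strand `-`.  `N` matches no motif symbol, so any
candidate containing `N` is rejected.

```{r g4}
scanG4(c(x = "GGGTGGGTGGGTGGG"))
```

## H-DNA candidates

Triplex-forming potential is usually scored with model-based systems
whose exact tables are tool-specific.  `scanHDNA()` instead implements a
transparent approximation built from the two sequence features all such
models share: a **mirror repeat** (the second arm is the reverse of the
first, up to `maxMismatch` mismatches, arms at least `minArm` bp,
spacer at most `maxSpacer` bp) and **homopurine/homopyrimidine
character** (combined arms at least `minPurity` purine *or* pyrimidine;
default 0.9).  A candidate scores `2 * armLength - 3 * mismatches`; the
mismatch penalty of 3 (> 2) guarantees that a candidate whose outermost
pair mismatches always scores below its trimmed version, so reported
hits never end on a mismatch.  From all candidates a non-overlapping
subset is selected greedily by decreasing score (ties leftmost, then
shortest).  Arm search is bounded at `maxArm` (default 25 bp) to keep
the maximal-interval search finite; (GAA)n tracts, the motif class of
interest, saturate this bound already at n >= 20.  Hits are
strand-symmetric by construction and reported on `+`.

This is a deliberate approximation: it reproduces the qualitative
behaviour (perfect and near-perfect homopurine mirror repeats score
high; mixed-composition repeats are rejected) without claiming to
reproduce any particular tool's P-values.

## Tandem repeats

`scanSTR()` locates maximal perfect arrays of a unit (e.g. `GAA`) with
at least `minCopies` copies; partial trailing copies are excluded.  The
score is the copy number, matching how engineered (GAA)n alleles are
described.

# Window profiles and spike-in normalization

`windowCounts()` counts reads into fixed 100-bp windows; each read
increments exactly one window -- the one containing its start
coordinate.  The start-coordinate rule is our documented choice where
a convention was needed: it is unambiguous and conserves counts (the
profile total equals the read count), which the tests assert.

`normalizeProfile()` makes profiles comparable between libraries:

$$\mathrm{value} = \frac{c}{T} \times
  \frac{\mathrm{ref}}{s/T} \times y$$

where \(c\) is the window count, \(T\) the library's uniquely mapped
experimental-genome reads, \(s\) its spike-genome reads, ref a
batch-level reference spike *fraction* (mean of \(s/T\); see
`batchSpikeFraction()`), and \(y\) the yield factor described below.
The middle factor rescales by the **relative abundance of the spike
genome**: because both \(c\) and \(s\) scale with sequencing depth, the
expression collapses to \(c \cdot \mathrm{ref} \cdot y / s\) and depth
cancels exactly.  Spiking a fixed proportion of foreign cells
(Drosophila S2 into DT40 at 1:4.2; DT40 into human cells at 1:10)
anchors the scale to per-cell material, so a genuine global increase in
R-loop load is visible rather than normalised away.  The choice of
reference constant only rescales all samples jointly; between-sample
ratios are invariant to it (asserted as a test).

**RNase H controls.**  RNase H degrades the RNA strand of DNA:RNA
hybrids -- experimental and spike hybrids alike -- so a treated sample's
read *composition* looks like the untreated one while its recovered
material is at least eightfold less.  The read counts cannot see this
loss; the measured relative recovery can.  Each library therefore
carries a `yieldFactor` (1 untreated, 1/8 by default for RNase H), and
the normalization multiplies by it, so the corrected RNase H track
displays the genuinely low residual signal.  The synthetic generator
models exactly this: treated libraries attenuate experimental *and*
spike signal eightfold, and the yield-corrected profile recovers the
residual truth (a test asserts the recovered ratio within 10%).

# Peak calling and peak heights

Real-data peaks are expected from a dedicated caller (e.g. MACS2) and
ingested as BED; `callPeaksSimple()` exists so synthetic end-to-end runs
are self-contained.  It thresholds a normalized profile at `fold`
(default 5) times the median nonzero window, keeps runs of at least
`minWindows` (default 2) windows, and merges runs separated by at most
`mergeGap` (default 200 bp).

Peak height normalization follows the spike-read convention: raw height
times \(\mathrm{ref}/s\) with a *count* reference
(`batchSpikeReads()`).  Raw heights are reported in read-count units --
the caller undoes the profile's linear normalization factor -- so the
spike correction is applied exactly once.  Because raw counts and spike
counts share the library's depth, depth again cancels, and the
normalized height ratio between conditions estimates the true
per-cell signal ratio; the synthetic experiment recovers a planted
two-fold change within 15%.

# Comparing two conditions

`matchPeaks()` reproduces standard interval semantics: two peaks match
if they share at least 1 bp (`overlap` mode), or additionally if their
gap is at most `maxGap` (default 1 kb, `proximity` mode); all
coordinates are half-open at the file boundary, so `[100,200)` and
`[200,300)` do not overlap but have gap 0.  Matching is one-to-one and
greedy by increasing gap, then decreasing overlap, with leftmost
tie-breaks -- keeping the shared fraction well defined.  Shared
fractions are reported relative to either set and to their union, since
"percent shared" is ambiguous otherwise.

`mannWhitney()` compares height distributions two-sidedly: exact by
complete enumeration of labelings (handling ties) for
`nA + nB <= 16`, and a tie-corrected normal approximation with
continuity correction otherwise.  The enumeration threshold of 16 keeps
the exact path under `choose(16, 8) = 12870` evaluations.  Group
summaries carry the median, interquartile range and inner fences
(quartile +/- 1.5 IQR), the statistics a violin plot draws.
`regressHeights()` fits matched heights on the log10 scale, where a
uniform k-fold change is intercept `log10(k)` at slope 1, directly
comparable to a 1:1 line.

# Gene association

`genesWithFeature()` applies one overlap rule everywhere: a gene counts
if any feature overlaps it by at least 1 bp, or lies within `maxGap`
when positive (the same 1-kb proximity rule serves the extragenic
analysis with the roles swapped).  `hypergeomEnrichment()` tests
whether peak-bearing genes are enriched for motif-bearing genes:
upper-tail \(P(X \ge k)\) for
\(X \sim \mathrm{Hypergeometric}(N, K, n)\) via `phyper()`, which works
in log space internally; an exhaustive draw-enumeration oracle verifies
every case with \(N \le 12\).

`metageneDistribution()` maps each peak midpoint onto a scaled gene
coordinate: `flankBins` bins over a fixed upstream flank (default 2 kb
in 20 bins), `bodyBins` over the body rescaled to 0--1 (default 40),
and the downstream flank, strand-aware.  Midpoint assignment avoids
double-counting wide peaks; overlapping genes are flattened first, and
a peak in several gene windows goes to the nearest gene.  Fractions are
relative to *all* peaks, so the profile sums to the fraction of peaks
within the gene +/- flank universe.  Flank width and bin counts are
parameters because promoter/terminator extents are conventions, not
measurements.

# The fluctuation model

A clone grows from a single expressing cell by synchronous doublings;
at each division every daughter of a high cell independently and
irreversibly switches to the silenced state with probability \(p\).
The number of high cells then follows
\(H_{t+1} \sim \mathrm{Binomial}(2 H_t, 1-p)\), which `simulateCohort()`
samples exactly, one binomial draw per generation -- an exact sample
from the lineage model at any population size the binomial sampler
supports, with a moment-matched normal draw beyond that.  The expected
loss-variant fraction after \(d\) divisions is
\(E[L] = 1 - (1-p)^d\) (asserted against simulation across a
\((p, d)\) grid).  The default of 40 divisions corresponds to 17--20
days of culture at a 10--12 h doubling time; it is a parameter because
it is an estimate, not a measurement.  Optional binomial subsampling
emulates scoring a finite number of cells by flow cytometry.

`estimateSwitchRate()` works from the cohort **median**, the summary
fluctuation assays report because it damps jackpot clones that switch
early.  Two inversions are offered.  The closed form
\(\hat p = 1 - (1 - m)^{1/d}\) (default) applies the mean-loss relation
to the median; it is simple and deterministic but systematically low by
about 10% at \(p = 0.005, d = 40\), because the loss-fraction
distribution is right-skewed and its median sits below its mean.  The
`"calibrated"` inversion removes that bias by inverting the
model-implied median itself: the curve \(p \mapsto \mathrm{median}(L)\)
is simulated once per division count under a fixed internal seed
(20,000 clones per grid point, 48 log-spaced rates) and inverted by
monotone interpolation.  Percentile-bootstrap confidence intervals push
each bootstrap median through the same inversion; with the calibrated
method the interval covers a planted rate in about 93--95% of cohorts
of 48 clones at the 95% level, which the acceptance suite verifies over
1,000 seeded replicates.  Cohort comparisons use one-way ANOVA or the
tie-corrected Kruskal--Wallis test (`compareCohorts()`), the two tests
conventionally applied to such cohorts, with Holm-adjusted pairwise
post-hocs.

# The synthetic-data generator

`SimulationConfig()` fixes the study conditions in one object.  The
defaults describe the experiment the pipeline targets: a 1 Mb
two-chromosome genome at 42% GC (about the avian gene-dense average);
60 planted G4s, 40 H-DNA mirror repeats and 10 (GAA)10 tracts; 600
genes; 300 true peaks of 800 bp, half centred on planted motifs;
wild-type expected peak height 500 reads against a 50,000-read uniform
background (roughly 10x local enrichment, a typical strong-peak
regime); a two-fold mutant elevation confined to motif-associated
peaks; spike material at the 1:4.2 cell ratio; eightfold RNase H
attenuation; and per-library depth jitter uniform on 0.6--1.6 to make
depth differences real rather than cosmetic.

Design choices worth noting:

* **Planting is exact.**  Motif instances are sampled from their
  defining grammars (G4 loops avoid G) and buffered with 8 bp of T --
  longer than the widest G4 loop -- so a planted interval can never
  chain into background G-runs; scanners recover planted intervals
  exactly, which the tests assert.
* **Relative risk is literal.**  Non-motif-centred peaks are placed by
  per-gene Bernoulli draws with probability proportional to
  `relativeRisk` for motif-bearing genes, so the configured value *is*
  the per-gene relative risk.  (Weighted sampling without replacement
  would compress it at realistic sampling fractions.)  The estimated
  enrichment \((k/n)/(K/N)\) approaches the planted risk when motif
  genes are a small minority -- the regime used in the recovery test --
  and is attenuated toward \(rN/(rK + N - K)\) otherwise, an intrinsic
  property of the odds, not an implementation artefact.
* **Spike reads are condition-independent** (per-cell spike material
  does not depend on the genotype) and scale only with each library's
  depth jitter; RNase H libraries attenuate experimental *and* spike
  signal, as the control chemistry does.
* Reads are fixed-length (75 bp) single-end intervals; sequencing
  error and alignment are out of scope, so no base-level simulation is
  attempted.

What the generator does *not* emulate -- and what passing tests
therefore do not show about real data: mappability and copy-number
structure, GC-dependent coverage bias, fragment-length effects,
replication-timing or chromatin covariates, peak-width changes between
conditions, and biological replicate variance beyond Poisson counting
and depth jitter.  Conclusions about those require real libraries.

# Numerical and interface conventions

Coordinates are 0-based half-open in every file (BED convention) and
1-based closed in every in-memory `GRanges`, converted only at the file
boundary by `rtracklayer` or the dedicated readers.  All randomness
sits behind explicit seeds (`SimulationConfig@seed`, `SwitchingModel@seed`,
function `seed` arguments); library code restores the caller's RNG
state.  Scanner output is deterministically sorted by (chrom, start),
so repeated runs produce byte-identical BED files.  Degenerate inputs
fail loudly with named offenders: reads on unknown chromosomes,
zero-spike libraries, double normalization, empty groups, constant
regressors, inconsistent enrichment counts.

Problem sizes in the shipped tests (1 Mb genomes, hundreds of peaks,
thousands of simulated cohorts) were chosen so the whole suite
exercises every claim at statistically meaningful scale while remaining
a routine desk run; all thresholds asserted in tests (e.g. fold-change
recovery within 15%, CI coverage >= 90%) were fixed from the study
design before the corresponding code was finalised.

# Known limitations

* `scanHDNA()` approximates triplex-forming potential; it does not
  reproduce any published scoring table, and its defaults were chosen
  to give qualitatively sensible length distributions, not calibrated
  P-values.
* `callPeaksSimple()` is a threshold caller for synthetic data; it has
  no background model, no fragment-size estimation and no broad-peak
  logic, and is not a substitute for a real caller on real data.
* The closed-form switch-rate inversion is biased low for skewed
  cohorts (see above); use `method = "calibrated"` when comparing
  against a known truth.
* Peak raw heights use the maximum window value; maxima of Poisson
  counts are slightly inflated at low depth, which biases recovered
  fold changes a few percent toward 1.  Height *ratios* remain within
  the documented 15% envelope at the default depth.
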