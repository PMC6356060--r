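# structloop

Quantitative analysis of R-loop formation at DNA
secondary-structure-forming sequences.

R-loops — DNA:RNA hybrids with a displaced single strand — accumulate
where transcription meets trouble. Sequences that fold into non-B DNA
structures (G-quadruplexes, H-DNA triplexes at mirror-repeat homopurine
tracts, (GAA)n repeats) stall replication forks, and in cells that
cannot reprime synthesis downstream of a block (loss of the
primase-polymerase PrimPol), persistent single-stranded gaps favour
excess R-loop formation and epigenetic instability of the surrounding
gene. `structloop` is for analysts who want to test this class of
hypothesis quantitatively from DRIP-seq / RNA DIP-seq style data: it
implements the motif scanning, spike-in-normalized signal and
peak-height quantification, two-condition comparison, gene-enrichment
and metagene statistics, and the fluctuation-assay model, plus a
synthetic-data generator with full ground truth for validation.

## The statistics at its core

* **Motif scanning.** G4 consensus `G3-5 N1-7 G3-5 N1-7 G3-5 N1-7 G3-5`
  with a deterministic leftmost-longest, non-overlapping match policy on
  both strands; H-DNA candidates as homopurine/homopyrimidine mirror
  repeats (arms ≥ 6 bp, spacer ≤ 8 bp, ≤ 1 mismatch, purity ≥ 0.9),
  scored `2·arm − 3·mismatches`; perfect tandem (GAA)n arrays.
* **Spike-in normalization.** Per-100-bp-window signal
  `(c/T) · (ref/(s/T)) · yield`: depth-normalized counts rescaled by the
  relative abundance of a foreign-genome spike (cells added at a fixed
  ratio, e.g. 1:4.2), with an RNase H yield correction (default 1/8)
  for treated controls whose global material loss is invisible to read
  composition. Peak heights are normalized by spike read number,
  `raw · ref/s`.
* **Two-condition comparison.** One-to-one peak matching under the
  ≥ 1 bp overlap rule (optionally ≤ 1 kb proximity), shared fractions,
  exact/tie-corrected Mann–Whitney U on heights, log10 height
  regression against the 1:1 line.
* **Enrichment.** Upper-tail hypergeometric test for motif-bearing
  genes among peak-bearing genes, `P(X ≥ k)`, `X ~ Hyper(N, K, n)`;
  strand-aware metagene profiles over scaled gene bodies with fixed
  flanks.
* **Fluctuation analysis.** Clones grow from one expressing cell;
  every daughter of a high cell switches irreversibly with per-division
  probability `p`, so high-cell counts follow
  `H(t+1) ~ Binom(2H(t), 1−p)` and `E[loss] = 1 − (1−p)^d`. The switch
  rate is estimated from the cohort median, by closed-form inversion or
  by a model-calibrated (bias-free) inversion, with percentile-bootstrap
  intervals; cohorts are compared by one-way ANOVA or Kruskal–Wallis.

## Worked example

```r
library(structloop)

# a synthetic two-condition experiment with known truth
res <- runSyntheticPipeline(SimulationConfig(seed = 11))

# do peaks coincide between wild type and primpol?
res$match$sharedFractionA
#> [1] 0.9910314

# is the mutant's height elevation confined to motif-associated peaks?
mm <- res$match$matches
assoc <- GenomicRanges::countOverlaps(res$peaks$wt[mm$indexA],
                                      res$genome$truth) > 0
median(mm$heightB[assoc] / mm$heightA[assoc])    # planted fold change: 2
#> [1] 1.821022
median(mm$heightB[!assoc] / mm$heightA[!assoc])  # planted: 1
#> [1] 0.981565

# are peak-bearing genes enriched for structure-forming motifs?
res$enrichment$pValue
#> [1] 3.120027e-32

# fluctuation assay: recover a planted switching rate from 48 clones
co <- simulateCohort(SwitchingModel(0.005, nClones = 48, seed = 1))
estimateSwitchRate(co, nDivisions = 40, method = "calibrated",
                   seed = 1)[c("pHat", "ciLower", "ciUpper")]
#> $pHat
#> [1] 0.004915211
#> $ciLower
#> [1] 0.004772679
#> $ciUpper
#> [1] 0.005202862
```

The matched-peak height ratio recovers the planted two-fold change at
motif-associated peaks while non-motif peaks stay at parity; the
hypergeometric p-value reflects the planted preference of peaks for
motif-bearing genes; and the calibrated estimator's interval covers the
planted per-division switching probability.

A thin command-line wrapper over the same functions lives in
`inst/scripts/structloop.R`
(`scan`, `simulate`, `quant`, `callpeaks`, `compare`, `enrich`,
`metagene`, `fluctuate simulate|estimate|compare`).

The methods vignette (`vignettes/structloop-methods.Rmd`) documents the
models, the normalization algebra, every tunable parameter with its
default and rationale, and what the synthetic data does and does not
emulate.

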