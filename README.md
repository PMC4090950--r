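# enhancerTE

Genome-wide analysis of the association between transposable-element
(repeat) annotations and chromatin-predicted enhancers, for regulatory
genomicists asking whether a repeat family has been exapted as
enhancers: are repeats concentrated in enhancer regions beyond a local
and a randomized background, do repeat-derived enhancers carry
enhancer-like chromatin profiles, are they enriched for
transcription-factor binding motifs relative to a resampled genomic
null, and does their local density predict gene expression level,
tissue specificity, and tissue-specific gene function?

## The statistics at the core

* **Repeat classification.** Each predicted enhancer is anchored at a
  single basepair; its span is the ±4 kb window around the anchor and
  its core the central 200 bp. A repeat containing an anchor *provides*
  an enhancer core (`MIR_ENHANCER`); a repeat overlapping a span is
  *enhancer-linked* (`ENHANCER_MIR`). Observed counts are compared to
  analytic or randomization expectations with the one-cell statistic
  `χ² = (O − E)² / E` (1 df, upper tail).
* **Metaprofiles and congruence.** Per-mark tag counts in 500 bp
  windows over ±10 kb, as fold over the genome-average count per
  500 bp; profiles are compared by Spearman's ρ weighted by the
  magnitude of the OLS slope (`score = ρ·|b|`), and marks ranked by
  score.
* **Empirical motif null.** Motif hits (PWM log-odds or IUPAC
  patterns, both strands, strand-distinct starts) in the target set
  versus 1,000 random pool samples matched in number and length;
  `Z = (χ − median)/sd` with a one-sided normal tail.
* **Tissue specificity.** `TS = Σ(1 − x_i)/(N − 1)` with max-normalized
  intensities (0 = uniform, 1 = single-tissue), plus Shannon entropy;
  gene-level repeat densities (gene ± 10 kb, whole-feature counts per
  bp) are regressed against expression responses over 100 equal-count
  bins (Pearson r).
* **Gene-set enrichment.** Genes within 100 kb of cell-type-specific
  features, tested against curated sets with the upper-tail
  hypergeometric distribution and BH adjustment.

A seeded synthetic-data generator (`syntheticConfig()`,
`generateAnnotations()`, `generateTracks()`, `generateExpression()`,
`generateSequences()`) plants all four effects with configurable
strength, so the full pipeline is testable without downloads.

## Worked example

```r
library(enhancerTE)
library(GenomicRanges)

cfg <- syntheticConfig(seed = 1)          # 2 x 5 Mb, 200 enhancers,
ann <- generateAnnotations(cfg)           # 5,000 repeats at fold 3
cls <- classifyRepeats(ann$enhancers, ann$repeats)
table(mcols(cls)$label)
#>     MIR_ENHANCER     ENHANCER_MIR NON_ENHANCER_MIR
#>               42             1784             3174

obs <- sum(mcols(cls)$label == "MIR_ENHANCER")
oneCellChiSq(obs, expectedCoreCount(ann$enhancers, ann$repeats, ann$layout))
#> EnrichmentReport (analytic): observed = 42, expected = 20.3, chi^2 = 23.3, p = 1.36e-06

spans <- enhancerSpans(ann$enhancers)
featureDensityFold(spans, ann$repeats, ann$layout)
#> [1] 2.963392
```

42 of 5,000 synthetic repeats contain an enhancer anchor against ~20
expected under uniform placement (χ² = 23.3), and the measured
repeat-density ratio inside enhancer spans recovers the planted
three-fold enrichment. The same machinery applied to the published
observed/expected pair (934, 669) gives:

```r
oneCellChiSq(934, 669)
#> EnrichmentReport (analytic): observed = 934, expected = 669, chi^2 = 105.0, p = 1.24e-24
```

`reproduceSynthetic(seed = 1)` runs every stage end to end (about ten
seconds) and returns the headline statistics; `runStage()` exposes the
same stages over files, and `inst/scripts/enhancerTE` is a thin
command-line wrapper (`enhancerTE classify --enhancers E.bed
--repeats R.bed --genome sizes.txt --out dir/ --seed 1`).

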