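---
title: "Methods: repeat-derived enhancer analysis with enhancerTE"
author: "enhancerTE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-derived enhancer analysis with enhancerTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scientific background

Transposable elements, and in particular ancient tRNA-derived SINE
families such as the mammalian-wide interspersed repeats (MIRs), are
unusually well conserved across mammalian genomes, and their local
density around genes correlates with tissue-specific expression. One
proposed resolution is that many of these repeats have been exapted as
transcriptional enhancers: they sit inside chromatin-predicted enhancer
regions, carry enhancer-characteristic histone-modification profiles,
donate transcription-factor binding sites (TFBSs), and their local
density predicts both the level and the tissue specificity of nearby
gene expression.

enhancerTE implements the complete analysis chain needed to test this
hypothesis on any combination of (i) enhancer predictions anchored at
single basepairs, (ii) repeat annotations, (iii) ChIP-seq signal
tracks, (iv) genome sequence-derived motif scans, (v) expression
matrices and (vi) curated gene sets — together with a seeded
synthetic-data generator so that every stage can be exercised and
validated without external downloads.

# The model, stage by stage

## Coordinates and interval algebra

All on-disk formats follow the BED convention (0-based, half-open);
internally everything is a `GRanges` and all overlap computation is
strand-agnostic. The occupancy density of a feature set in a region set
(`occupiedFraction()`) is the fraction of merged-region basepairs
covered by merged features; features overhanging a boundary contribute
only their overlapping basepairs, so the fraction is always in
\[0, 1\].

Local enrichment is measured against a *local genomic background*: for
each region a same-length window is drawn uniformly from the envelope
100–200 kb downstream of the region (mirrored upstream when the
chromosome ends first; infeasible loci are skipped with a warning).
The published description fixes only "100 kb downstream"; the uniform
\[offset, 2·offset\] envelope is this package's formalization — it
preserves the stated distance scale while making the draw well-defined
and seedable. Normalizing numerator and denominator by the genome-wide
average density leaves the ratio unchanged, so
`normalizedLocalEnrichment()` reports the plain density ratio.

## Classifying repeats against enhancers

An enhancer is anchored at a single predicted basepair; its span is the
±4 kb window around the anchor (the empirical extent of the
enhancer-characteristic chromatin pattern) and its core the central
200 bp. A repeat containing an anchor (half-open containment,
`start <= anchor < end`) *provides* an enhancer core
(`MIR_ENHANCER`); a repeat merely overlapping a span by ≥ 1 bp is
*enhancer-linked* (`ENHANCER_MIR`); everything else is
`NON_ENHANCER_MIR`. The labels are mutually exclusive and exhaustive,
repeats overlapping several spans count once, and an enhancer with
several linked repeats counts once in per-enhancer tallies.

Two null expectations are available:

* **Analytic, per repeat.** Anchors falling uniformly at random hit a
  repeat of length $L$ with probability $\approx n_{enh} L / G$, so the
  expected number of anchor-containing repeats is the genome-wide
  enhancer density times the *summed* (unmerged) repeat length. The
  unmerged sum matters: the observed statistic counts every annotated
  repeat separately, so two overlapping repeats sharing an anchor
  contribute two observations, and a merged-length expectation would be
  systematically low — we verified that the merged variant inflates the
  null chi-square in the calibration test.
* **Simulated, per enhancer.** `expectedEnhancersWithRepeats()` places
  random sites matched to the repeats in number and length (uniform per
  chromosome, weighted by chromosome length, overlaps permitted — the
  simplest null consistent with "equivalent in number and size") and
  counts spans overlapped by at least one site, averaged over
  replicates.

Significance uses the one-cell statistic $(O-E)^2/E$ with a 1-df
upper-tail chi-square. This is deliberately *not* the two-cell Pearson
test: the single-cell form is the one that reproduces the published
worked examples exactly (e.g. $(934-669)^2/669 \approx 105$), which the
acceptance suite checks for all four printed pairs.

## Chromatin metaprofiles and congruence

`metaprofile()` aggregates tag counts in 500 bp windows tiling a 20 kb
span centered on the feature midpoints and expresses each window as
fold enrichment over the genome-average count per 500 bp (total tags ÷
(genome length / window size)). Tags follow a point model (assigned by
start coordinate; a bedGraph interval contributes its start position at
its value's weight). Windows that fall off a chromosome end are dropped
from that window's average and reported.

Congruence between a canonical profile and a test profile is Spearman's
$\rho$ (average ranks for ties) weighted by the magnitude of the
ordinary-least-squares slope of the test profile on the canonical
profile: $score = \rho \, |b|$. Regressing the test profile on the
canonical one makes scores above 1 mean "congruent and stronger than
canonical". The slope enters by magnitude so that the correlation
alone carries the sign — an anti-correlated profile scores negatively,
as it should; the literal product $\rho b$ would return +1 for a
perfectly anti-correlated pair. `rankMarks()` orders marks by
descending score.

## Motif enrichment with an empirical null

Motifs are counted two ways, always on both strands, with the hit count
defined as the number of *strand-distinct start positions* (a
palindromic site counts once):

* **PWM scanning** (`scanPwm()`): log-odds against a uniform 0.25
  background with pseudocount 0.01 added to numerator and background
  before the log (so a background-probability base — and any `N` —
  contributes exactly 0); a position is a hit when either strand
  reaches `thresholdFrac` (default 0.8) of the maximum achievable
  score. The threshold and background are explicit configuration; with
  a 0/1 matrix and threshold 1.0 the scan reduces to exact string
  matching, which is property-tested.
* **IUPAC pattern scanning** (`scanRegex()`): degenerate-code matching
  of the pattern and its reverse complement on the forward strand,
  validated against a full window-enumeration oracle.

`empiricalMotifTest()` compares the observed target-set count to a null
distribution built from `nReps` (default 1,000) random samples drawn
from a background sequence pool, matched to the target set in number
and per-sequence length (without replacement within a replicate, with
replacement across replicates; longer pool sequences are trimmed at a
random offset). Following the published procedure the empirical
expectation is the null *median*; the dispersion is the null sample
standard deviation (the only dispersion the procedure yields), giving
$Z = (\chi - \tilde{\mu})/\sigma$ and a one-sided normal upper tail. A
null with zero spread is flagged degenerate and no p-value is emitted.
The acceptance suite verifies type-I calibration at $\alpha = 0.05$
over 400 seeded null runs.

## Expression association

The tissue-specificity index of a gene with intensities $x_1 \dots x_N$
(max-normalized) is $TS = \sum_i (1 - x_i)/(N-1)$: 0 for uniform, 1 for
single-tissue expression, scale-invariant. Shannon entropy
$H = -\sum p_i \log_2 p_i$ over the normalized profile is the
complementary measure (low entropy = specific); the two are strongly
anti-correlated on random profiles, which is property-tested.

`geneFeatureDensity()` counts features with ≥ 1 bp overlap of the gene
body ± 10 kb (clipped at chromosome ends, with the clipped length as
denominator) — whole-feature counts per bp, not bp occupancy, following
the published wording. `binnedRegression()` sorts genes by density,
splits them into 100 *equal-count* bins (quantile bins; ties broken by
stable gene order) and correlates per-bin mean density with per-bin
mean response (Pearson, two-sided, on the bin pairs). Equal-count bins
were chosen over equal-width because repeat densities are highly
skewed — most genes have density 0, and equal-width binning would leave
most bins empty. Computing significance on the 100 bin pairs is the
literal reading of the published procedure; it is less conservative
than a gene-level test, which users can obtain by setting `nBins` to
the gene count.

## Gene-set enrichment

Cell-type-specific features are the exact-coordinate set difference of
two feature sets (present in one condition, absent in the other). Genes
are linked to features within 100 kb edge-to-edge (overlap = distance
0); a TSS-anchored mode is available since the published wording fixes
only the distance. Overlap with curated gene sets is tested with the
upper-tail hypergeometric distribution, $P(X \ge k)$ including the
observed overlap, evaluated in log space via `phyper`; the universe
size is a configuration input (the source analysis itself reports two
slightly different universe counts), defaulting to the supplied gene
model, and q-values are Benjamini–Hochberg across the tested sets.

# The synthetic-data generator

`syntheticConfig()` fixes the study conditions; all generators are pure
functions of the config (identical outputs per seed). Defaults: 2
chromosomes × 5 Mb, 200 enhancer anchors (uniform with ≥ 8 kb spacing
and a 25 kb end margin), 5,000 repeats with log-normal lengths (median
180 bp, log-sd 0.5, floored at 50 bp — the scale of real SINE
annotations), 500 non-overlapping genes, 6 tissues. These sizes keep
the full pipeline comfortably inside two minutes on a single CPU while
leaving every planted effect recoverable.

* **Repeat placement.** Start positions are drawn from a two-component
  mixture with relative density `enhancerRepeatFold` (default 3) inside
  enhancer spans versus 1 outside. The planted fold is recovered as the
  *count-density* ratio (starts per bp in spans over starts per bp
  elsewhere, `featureDensityFold()`); a bp-occupancy ratio saturates
  when repeats are dense enough to merge and underestimates the fold.
* **Signal tracks.** Active marks are uniform Poisson background
  (`tagRate` = 0.01 tags/bp) plus a Gaussian surplus (σ = 1 kb) at each
  anchor, with the per-enhancer surplus solved analytically so that the
  central 500 bp metaprofile window reaches `bumpHeight` (default 5)
  fold over the track's own genome average — naively planting
  `bumpHeight` times the background underestimates the profile because
  the surplus itself inflates the genome average. The repressive mark
  is background thinned multiplicatively to `depletionDepth` (default
  0.2) at the anchor; the small residual bias from the thinned total is
  below Monte-Carlo resolution at the default depth.
* **Expression.** Per-gene tissue profiles are Dirichlet with a
  symmetric concentration that decays exponentially in
  `tsDensityBeta` × (max-scaled enhancer-repeat density), times a
  log-normal magnitude. Low concentration gives sparse, tissue-specific
  profiles, so TS rises with density at a rate set by β; β = 0 yields
  exact independence. Dirichlet generation was chosen because it
  produces valid nonnegative profiles with a single coupling knob.
* **Sequences.** Repeat sequences are i.i.d. nucleotides at the
  configured GC content (0.41, the human genome-wide value), with the
  configured motif (default `TGACTCA`, the AP-1 consensus) planted at
  rate 0.5 in enhancer-associated repeats and 0.05 elsewhere.

What the generator does **not** emulate: real MIR sequence content
(tRNA-derived consensus and its divergence), chromosome-scale
heterogeneity (GC/gene-density covariation, assembly gaps),
heavy-tailed ChIP-seq backgrounds, replicate structure, or
probe-to-gene mapping noise. Passing tests therefore demonstrate that
the statistical machinery recovers planted structure of realistic
magnitude — not that any particular biological claim holds on real
data.

# Numerical choices and degenerate inputs

* PWM pseudocount 0.01 before the log transform avoids −∞ scores; PWM
  thresholds are compared with a 10⁻⁹ slack so "score equals the
  maximum" is robust to floating-point rounding.
* Zero-variance profiles (congruence), zero background densities
  (enrichment folds), all-zero expression profiles (TS/entropy),
  constant bin means (binned regression), and zero-spread motif nulls
  are rejected or flagged `NA` rather than silently propagated.
* Malformed intervals (start ≥ end) are rejected naming the offender;
  spans and flanks are clipped at chromosome ends with the clipped
  length used in denominators, and clipping is reported.
* Background-window sampling near chromosome ends mirrors upstream; a
  locus with no feasible placement is skipped with a warning rather
  than aborting a whole run.
* Child seeds for independent random streams are derived with a fixed
  linear map and kept below 2³¹.

# Test and validation sizes

The shipped suite validates each operation against independent oracles
(per-base boolean arrays, window enumeration, binomial-coefficient
sums) on hundreds of random small instances; calibration runs use 400
seeded motif-null tests at 200 resamples each, 100 seeded unplanted
genomes for the chi-square null, and 10 seeded fold-3 genomes at 20,000
repeats for observed/expected recovery. For the observed/expected
recovery the synthetic genome uses 2 × 100 Mb chromosomes and 600
enhancers so that enhancer spans are a small fraction of the genome, as
they are in real genomes: when spans occupy a sizable genome share, the
planted enrichment inflates the genome-wide mean density itself, and
the observed/expected ratio is bounded below the planted fold
($f / (1 + (f-1)S/G)$) — with the default toy genome ($S/G = 0.16$)
the ratio cannot exceed ≈ 2.3 for $f = 3$, which is a property of the
statistic, not an implementation error. The end-to-end integration
check is a single seeded run, as the per-seed variability of the
smallest counts (tens of repeat-provided cores) spans an order of
magnitude in p-value; the powered linkage statistic carries the
stringent significance assertion.

# Known limitations

* The analytic linked-repeat expectation neglects chromosome-boundary
  effects (a repeat cannot straddle a chromosome end); negligible for
  spans far from ends, slightly conservative otherwise.
* The metaprofile point model ignores fragment length; a
  coverage-interval model would shift profiles by half a fragment.
* `empiricalMotifTest()` requires, for every target length, an unused
  pool sequence at least that long within each replicate; callers with
  heavy-tailed target lengths should trim the target set (the
  end-to-end runner caps targets at the pool's median length).
* The whole pipeline is single-threaded by design; the intended scale
  (≤ 10⁵ features, ≤ 10⁷–10⁸ bp synthetic genomes) runs in seconds to
  minutes.
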