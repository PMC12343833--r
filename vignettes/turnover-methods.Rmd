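---
title: "Measuring TOP1 cleavage-complex turnover in chromatin context: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring TOP1 cleavage-complex turnover in chromatin context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

DNA topoisomerase 1 (TOP1) relaxes supercoils by nicking one strand through a
covalent TOP1:DNA cleavage complex (TOP1cc). Normally transient, TOP1ccs are
stabilized by camptothecin (CPT), and their accumulation is cytotoxic. Sites of
high torsional stress — above all the transcription start sites (TSS) of
highly expressed genes — concentrate TOP1 yet show *depleted* TOP1cc signal,
implying active, chromatin-assisted clearance. The histone variant
macroH2A1.1, the only nucleosome component that binds poly(ADP-ribose),
co-occupies TOP1-enriched chromatin and promotes TOP1cc turnover; its loss
lets damage-induced TOP1ccs accumulate, most strongly at highly transcribed
genes and at TOP1 peaks with high macroH2A1.1 occupancy.

`topoturn` implements the genomic analysis layer needed to quantify this
biology from sequencing data: normalized coverage tracks, the
turnover statistic, stratified metaprofiles, and colocalization statistics —
plus a synthetic-data generator with known ground truth, because the original
human datasets are controlled-access and desk-scale reproduction must not
depend on them.

## The turnover statistic

CAD-Seq (covalent adduct detection sequencing) maps fragments carrying
catalytically engaged TOP1. Two conditions are compared:

* **steady state** — a brief (5') CPT pulse under proteasome inhibition,
  freezing the standing TOP1cc population;
* **prolonged damage** — 30' CPT without proteasome inhibition, so trapping
  and repair proceed simultaneously.

The per-bin turnover statistic is

$$\Delta \mathrm{TOP1cc} = \log_2
  \frac{C_{30'} + \epsilon}{C_{5'} + \epsilon},$$

where $C$ are spike-scaled, replicate-combined coverage values and
$\epsilon$ is a pseudocount (default 0.5 per bin). $\Delta\mathrm{TOP1cc} > 0$
means TOP1ccs accumulate in response to damage — clearance is impaired.

The documented pipeline order is *merge replicate fragments (spike counts
summed) → blacklist removal → binned coverage → spike-in scaling → log2
ratio*, enforced by the normalization-state tags on `CoverageTrack` objects:
`spikeInScale()` only accepts raw tracks, `combineReplicates()` requires a
shared state, and `log2RatioTrack()` refuses Z-normalized inputs.

### Why the ratio is never Z-normalized before statistics

Z-normalizing a track recenters it at zero and produces negative values, so a
log2 ratio *of Z-normalized inputs* is undefined, and Z-normalizing the ratio
itself would destroy the sign interpretation ("> 0 = accumulation"). The
package therefore computes all turnover statistics on the unnormalized log2
ratio of spike-scaled tracks; `znormalizeTrack()` may be applied to the ratio
track afterwards purely for display (putting profile plots from different
experiments on one axis), never before group comparisons.

## Stratified analyses

* **Expression quartiles** (`assignExpressionQuartiles()`, `deltaByGroup()`):
  genes are ranked by expression, ties broken by stable table order, ranks
  split as evenly as possible into Q1 (bottom 25%) … Q4 (top 25%). Each gene
  contributes the mean $\Delta\mathrm{TOP1cc}$ over TSS ± 250 bp (bp-weighted
  across partial bins; fully masked windows are excluded and counted). All six
  quartile pairs are compared with two-sided Mann–Whitney U tests, reported
  without multiplicity adjustment (a Benjamini–Hochberg option exists but is
  off by default, matching the convention of reporting raw pairwise p values).
* **Occupancy tertiles** (`stratifyBySignalTertiles()`): TOP1 peaks are scored
  by mean macroH2A1.1 coverage over the peak (length-robust; a max-based score
  is available), ranked with stable tie-breaks, and the top and bottom thirds
  are kept; the middle third is discarded.
* **Mann–Whitney U** (`mannWhitneyU()`): exact two-sided p by full enumeration
  of rank assignments when the pooled size is ≤ 12 without ties, otherwise the
  normal approximation with tie correction and continuity correction. The
  exact path makes small-sample tests reproducible to the rational value
  (e.g. {1,2} vs {3,4} gives p = 1/3).

## Colocalization

The base-pair Jaccard index — intersection over union after flattening — is
compared against a permutation null: in each of `nShuffles` iterations
(default 1000) *both* interval sets are independently relocated, each interval
placed uniformly among its valid start positions, chromosomes weighted by
their number of valid starts, blacklist placements rejected and redrawn.
Shuffled intervals may overlap one another, mirroring the default of the
standard interval-shuffling tool. The empirical p value uses the add-one
estimator $(1 + \#\{J_{null} \ge J_{obs}\})/(n + 1)$, so it is never zero and
is exactly uniform under the null. TSS-proximity classes use the peak
midpoint: ≤ 3 kb to the nearest TSS is proximal, > 10 kb distal, the 3–10 kb
gap is excluded by construction.

## Metaprofiles

`computeSignalMatrix()` is the reference-point matrix operation: positional
bins spanning [−upstream, +downstream) around each anchor, cells being
bp-weighted means of the track. Minus-strand anchors are orientation-flipped
so column 1 is always 5′-most; windows running off a chromosome end are
missing (`NA`), never zero-filled — zero-filling would fabricate depletion at
chromosome ends. TSS-distal peak anchors are treated as unstranded, since
strand orientation is only meaningful for TSS-proximal anchors.
`meanProfile()` takes column means over non-missing cells and optionally
smooths with LOESS: degree-1 local regression, tricube kernel, no robustness
iterations, window = nearest ⌈span·n⌉ points (span 0.15 is a sensible default
for TSS profiles; finer detail wants ~0.025). Degree-1 LOESS reproduces an
exactly linear profile unchanged, which the tests exploit.

## The synthetic study

`simScenario()` fixes the study conditions; `buildSyntheticGenome()` and the
two fragment simulators realize them with a recorded ground truth
(`SimTruth`), so every downstream estimate has a known target.

Default conditions and their rationale:

| parameter | default | rationale |
|---|---|---|
| genome | 4 chromosomes × 2 Mbp | large enough for ~kb-scale features at realistic densities; small enough that the suite runs in minutes on one CPU |
| genes | 400, log-normal expression (meanlog 1, sdlog 1) | RNA-seq-like right-skewed expression |
| TOP1 hotspots | 300, width ≈ N(1000, 200) bp, 70% TSS-linked (sampled ∝ expression), disjoint | TOP1 concentrates at active TSSs; the remainder are distal (> 10 kb from any TSS) |
| macroH2A1.1 domains | 180, width ≈ N(5000, 1000) bp, placed so ~50% of hotspots are covered | broad domains overlapping a substantial hotspot fraction, leaving an uncovered contrast group |
| blacklist | 0.5% of the genome in 2 kb intervals | artifact regions to exercise exclusion logic |
| CUT&RUN | 10⁵ fragments, length ≈ N(150, 25) bp, enrichment fold 20, spike fraction 1% | nucleosome-scale fragments; the mixture weight is chosen so the target/background density ratio equals the fold exactly |
| CAD-Seq | λₛ = 0.2 fragments/bp/hotspot, background 10⁻³/bp, length ≈ N(1000, 200) bp | ~1 kb sonication fragments; per-hotspot steady counts of ~200 keep ratio estimates stable |
| turnover | δ = 1 (both genotypes), ρ = 1 | see below |
| track bins | 10 bp (profiles); 10 kb windows for correlations | profile-grade vs genome-scan resolution |

The generative turnover rule: per hotspot $h$ with normalized expression
$e_h$ and binary occupancy $m_h$, the prolonged-damage intensity is

$$\lambda_s w_h \bigl(1 + \delta_{genotype}\, e_h\,
   (1 - \rho\, m_h\, [genotype = control])\bigr).$$

$e_h$ is the empirical-CDF rank of the linked gene's expression (in (0, 1];
0 for distal hotspots) — a monotone, scale-free normalization that keeps the
closed-form expectation $\log_2(1 + \delta e_h)$ well inside the dynamic
range. The genotype effect is modeled as *loss of protection*: both genotypes
share δ, and ρ = 1 means macroH2A1.1-covered hotspots accumulate nothing in
control cells. This is the simplest rule under which all observed contrasts
coexist: knockdown accumulation rising with expression, near-zero control
signal at covered hotspots, and a knockdown-vs-control gap that is large at
high-occupancy and absent at low-occupancy peaks. Setting δ to differ by
genotype instead would make the knockdown arm occupancy-independent *and*
erase the tertile contrast, so it is not used.

Spike-in counts: CUT&RUN libraries have a fixed total depth and draw the
spike count binomially from the spike fraction. CAD-Seq libraries draw the
spike count as Poisson around spikeFraction × the expected steady-state
library size, *independent of the genomic adduct load* — a spike-in is a
fixed exogenous reference, and coupling it to the signal would fold the
global damage factor into the normalizer and bias every ratio.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis consumes: enriched
fragment midpoints over defined intervals, Poisson library noise, spike-in
counts, condition/genotype intensity contrasts, blacklist artifacts. It does
**not** model sequence (no mappability or GC structure), fragment-level
duplicates, chromatin-state correlations beyond the placed domains, replication-
associated damage, or peak-calling uncertainty (true intervals stand in for
called peaks). Passing recovery tests therefore demonstrates correctness of
the estimators under the stated model, not robustness to every artifact of
real libraries.

## Numerical choices

* Coordinates are handled as `GenomicRanges` (1-based closed) internally;
  BED/bedGraph I/O converts to and from the on-disk 0-based half-open
  convention at the boundary.
* Blacklist removal drops any record overlapping a blacklist interval by
  ≥ 1 bp — conservative, order-independent, idempotent.
* Bin values are mean per-base depth; a chromosome's short last bin keeps the
  nominal bin width in the denominator so total mass (Σ value × bin width)
  equals total fragment bp exactly.
* Z-normalization uses the population SD over all defined bins.
* Ratio bins where both inputs are exactly 0 are masked (`NA`), not 0:
  absence of signal in both conditions carries no turnover information.
* All rank-based splits (quartiles, tertiles) break ties by stable input
  order, so results are deterministic on tied data.
* Shuffling and simulation use R's RNG seeded once per entry point; every
  stochastic result records its seed, and identical seeds give byte-identical
  statistical outputs.

## Problem sizes used by the test suite

Oracle-equivalence tests compare against per-base brute force on genomes of a
few kb (hundreds of randomized cases). Permutation calibration uses 200
independent datasets at 199 shuffles each. Parameter recovery runs 100
replicate library simulations of the default scenario per genotype arm and
checks the mean recovered ΔTOP1cc at covered Q4 hotspots against
$\log_2(1+\delta e)$ within 3 Monte-Carlo standard errors. The end-to-end
demonstration (`runDemo()`) is exercised on five seeds at 1000 shuffles.
These sizes were chosen so the whole suite completes in minutes on one CPU
while keeping every check statistically meaningful.

## Known limitations

* Peak calling is out of scope; peaks/domains are inputs (or simulator truth).
* The shuffle null is uniform within chromosome bounds minus the blacklist;
  it is not GC- or mappability-matched.
* `binnedCorrelation()` drops windows where any track is undefined
  (complete cases), which slightly favors well-covered regions.
* The turnover model treats occupancy as binary at the hotspot midpoint;
  graded occupancy is not modeled.
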