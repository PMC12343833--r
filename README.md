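# topoturn

Genomic analysis of **TOP1 cleavage-complex (TOP1cc) turnover in chromatin
context**, for epigenomics researchers studying how chromatin composition —
in particular the histone variant macroH2A1.1 — shapes the resolution of
topoisomerase 1 lesions at sites of transcription-associated torsional
stress.

DNA topoisomerase 1 relaxes supercoils through a covalent TOP1:DNA cleavage
complex. Camptothecin (CPT) traps this intermediate; whether trapped TOP1ccs
are cleared or accumulate depends on the local chromatin. `topoturn`
implements the computational layer of that biology:

* **Coverage tracks** — binned, blacklist-filtered, spike-in-normalized
  fragment coverage (`coverageFromFragments()`, `spikeInScale()`,
  `znormalizeTrack()`, `combineReplicates()`, `binnedCorrelation()`).
* **The turnover statistic** — per bin,

  ```
  ΔTOP1cc = log2( (C_30'CPT + ε) / (C_5'CPT + ε) )
  ```

  the log2 ratio of prolonged-damage over steady-state TOP1cc coverage
  (`log2RatioTrack()`, `makeDeltaTrack()`); ΔTOP1cc > 0 means damage-induced
  TOP1cc accumulation, i.e. impaired clearance.
* **Stratified statistics** — per-gene mean ΔTOP1cc over TSS ± 250 bp split
  by expression quartiles Q1–Q4 with all pairwise two-sided Mann–Whitney U
  tests (`deltaByGroup()`, `mannWhitneyU()`), and TOP1 peaks split into top
  vs bottom macroH2A1.1-occupancy tertiles (`stratifyBySignalTertiles()`).
* **Colocalization** — base-pair Jaccard index of two interval sets against
  a permutation null built by randomly relocating both sets within genome
  bounds, avoiding the blacklist, with add-one empirical p values
  (`jaccardIndex()`, `shuffleIntervals()`, `permutationColocalization()`);
  TSS-proximal (≤ 3 kb) / TSS-distal (> 10 kb) peak classification
  (`classifyTssProximity()`).
* **Metaprofiles** — strand-aware reference-point signal matrices and
  LOESS-smoothed average profiles (`computeSignalMatrix()`, `meanProfile()`,
  `regionMeanSignal()`).
* **Synthetic data with ground truth** — `simScenario()`,
  `buildSyntheticGenome()`, `simulateCutrunFragments()` (CUT&RUN with
  E. coli-style spike-in) and `simulateCadseqFragments()` (CAD-Seq under
  steady-state and prolonged damage, control and macroH2A1.1-knockdown
  genotypes), so the full pipeline is testable without controlled-access
  human data.

Standard formats are supported throughout: chrom.sizes, BED3/BED6 and
bedGraph (`readChromSizes()`, `parseBed()`, `writeBed()`, `writeBedGraph()`).

## Worked example

`runDemo()` executes the default synthetic study end to end — genome and
ground truth, CUT&RUN and CAD-Seq libraries, normalized tracks, and the four
computational signatures of macroH2A1.1-dependent TOP1cc turnover:

```r
library(topoturn)
res <- runDemo("demo_out", seed = 1)
cat(readLines(file.path("demo_out", "report.txt")), sep = "\n")
```

```
Synthetic-pipeline signature report
seed: 1
[PASS] (i) colocalization: observed Jaccard 0.1592 vs null mean 0.0286, empirical p 0.000999
[PASS] (ii) quartile monotonicity: KD medians 0.209 <= 0.386 <= 0.656 <= 0.875; Q4 vs Q1 p = 2.34e-08
[PASS] (iii) tertile contrast: KD-vs-control gap 0.562 (1.1-high) vs 0.024 (1.1-low)
[PASS] (iv) IgG hotspot enrichment ratio 1.016
```

Reading the report:

* **(i)** macroH2A1.1 domains overlap TOP1 hotspots five-fold more than
  randomly relocated intervals of the same sizes (Jaccard 0.159 vs 0.029);
  no permutation among 1000 reaches the observed value, so the add-one
  empirical p is 1/1001.
* **(ii)** in the knockdown arm, median ΔTOP1cc at the TSS rises
  monotonically across expression quartiles (0.21 → 0.87): the more a gene
  is transcribed, the more TOP1cc accumulates without macroH2A1.1.
* **(iii)** the knockdown-vs-control ΔTOP1cc gap is concentrated at
  macroH2A1.1-high TOP1 peaks (0.56) and essentially absent at
  macroH2A1.1-low peaks (0.02) — the protective effect is local.
* **(iv)** the IgG control library shows no hotspot enrichment (ratio ≈ 1),
  confirming assay specificity in the simulation.

`demo_out/` also receives the ΔTOP1cc bedGraph tracks, a LOESS-smoothed TSS
profile, per-gene quartile tables, the Jaccard null distribution, and a JSON
manifest recording every parameter and seed needed to re-run identically.

## Package layout

The methods vignette (`vignettes/turnover-methods.Rmd`) documents the
turnover model, the pipeline order and its enforcement via
normalization-state tags, the synthetic-data generator's defaults and their
rationale, numerical conventions, and known limitations.
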