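Package: topoturn
Title: TOP1 Cleavage-Complex Turnover and Chromatin Colocalization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genomic analysis toolkit for studying topoisomerase 1 cleavage-complex
    (TOP1cc) turnover in its chromatin context. Builds spike-in-normalized binned
    coverage tracks from aligned fragment sets, computes the delta-TOP1cc turnover
    statistic (log2 ratio of prolonged-damage over steady-state TOP1cc signal),
    stratifies turnover by gene-expression quartiles and by histone-variant
    occupancy tertiles with rank-based tests, measures interval-set colocalization
    by the base-pair Jaccard index against a constrained permutation null, and
    produces strand-aware reference-point signal matrices with LOESS-smoothed
    average profiles. A first-class synthetic-data module simulates CUT&RUN and
    covalent-adduct-detection (CAD-Seq) fragment libraries with known ground truth
    so the whole pipeline is testable end to end without controlled-access data.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
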