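test_that("genome construction is reproducible and honors its constraints", {
  sc <- smallScenario(3L)
  t1 <- buildSyntheticGenome(sc)
  t2 <- buildSyntheticGenome(sc)
  expect_identical(truthGenes(t1), truthGenes(t2))
  expect_identical(as.data.frame(truthHotspots(t1)),
                   as.data.frame(truthHotspots(t2)))

  hs <- truthHotspots(t1)
  expect_identical(length(GenomicRanges::findOverlaps(hs, drop.self = TRUE)),
                   0L)  # hotspots disjoint
  # TSSs avoid the blacklist
  tss <- tssAnchors(truthGenes(t1), truthLayout(t1))
  expect_identical(
    length(GenomicRanges::findOverlaps(tss, blacklist(truthLayout(t1)))), 0L)
  # recorded occupancy matches domain coverage of midpoints
  m <- GenomicRanges::countOverlaps(midpointAnchors(hs), truthDomains(t1)) > 0
  expect_identical(mcols(hs)$m, as.integer(m))
  # TSS-linked hotspots carry positive normalized expression, distal zero
  expect_true(all(mcols(hs)$e[mcols(hs)$is_tss] > 0))
  expect_true(all(mcols(hs)$e[!mcols(hs)$is_tss] == 0))
})

test_that("degenerate and saturated scenarios behave as specified", {
  empty <- buildSyntheticGenome(
    simScenario(chromLengths = c(chr1 = 1e5), nGenes = 0L, nHotspots = 0L,
                nDomains = 0L, blacklistFraction = 0, rngSeed = 1L))
  expect_identical(nrow(truthGenes(empty)), 0L)
  expect_length(truthHotspots(empty), 0L)
  expect_identical(unname(chromLengths(truthLayout(empty))), 100000L)

  # cover fraction 1 with enough domains: every hotspot midpoint covered
  full <- buildSyntheticGenome(
    simScenario(chromLengths = c(chr1 = 1e6, chr2 = 1e6), nGenes = 50L,
                nHotspots = 20L, nDomains = 25L, hotspotCoverFraction = 1,
                rngSeed = 2L))
  expect_true(all(mcols(truthHotspots(full))$m == 1L))
})

test_that("expression samples match the log-normal scenario parameters", {
  sc <- simScenario(chromLengths = c(chr1 = 5e6, chr2 = 5e6), nGenes = 10000L,
                    nHotspots = 0L, nDomains = 0L, exprMeanlog = 1,
                    exprSdlog = 1, rngSeed = 4L)
  lg <- log(truthGenes(buildSyntheticGenome(sc))$expression)
  n <- length(lg)
  expect_lt(abs(mean(lg) - 1), 3 / sqrt(n))             # SE of mean = sd/sqrt(n)
  expect_lt(abs(sd(lg) - 1), 3 / sqrt(2 * n))           # SE of sd ~ sd/sqrt(2n)
})

test_that("CUT&RUN libraries conserve counts and recover the enrichment fold", {
  truth <- buildSyntheticGenome(smallScenario(6L))
  fs <- simulateCutrunFragments(truth, "TOP1", seed = 2L)
  expect_identical(length(fragments(fs)) + spikeInCount(fs),
                   truthScenario(truth)@cutrunFragments)
  # determinism
  fs2 <- simulateCutrunFragments(truth, "TOP1", seed = 2L)
  expect_identical(as.data.frame(fragments(fs)), as.data.frame(fragments(fs2)))
  expect_identical(spikeInCount(fs), spikeInCount(fs2))

  zero <- simulateCutrunFragments(truth, "TOP1", seed = 2L, nFragments = 0L)
  expect_length(fragments(zero), 0L)
  expect_identical(spikeInCount(zero), 0L)
  expect_error(simulateCutrunFragments(truth, "H3K27me3", seed = 1L))

  # coverage over true hotspots vs distal background ~ enrichment fold
  tr <- coverageFromFragments(fs, truthLayout(truth), 50L)
  hs <- truthHotspots(truth)
  ln <- chromLengths(truthLayout(truth))
  flank <- GenomicRanges::reduce(
    GenomicRanges::resize(hs, width(hs) + 2000L, fix = "center"))
  genome <- GRanges(names(ln), IRanges(1L, ln))
  bgw <- GenomicRanges::setdiff(genome, flank)
  fold <- mean(regionMeanSignal(tr, hs)) /
    weighted.mean(regionMeanSignal(tr, bgw), width(bgw))
  expect_gt(fold, 15)
  expect_lt(fold, 25)

  # IgG is flat over hotspots
  igg <- simulateCutrunFragments(truth, "IgG", seed = 3L)
  tri <- coverageFromFragments(igg, truthLayout(truth), 50L)
  foldIgg <- mean(regionMeanSignal(tri, hs)) /
    weighted.mean(regionMeanSignal(tri, bgw), width(bgw))
  expect_lt(abs(foldIgg - 1), 0.35)
})

test_that("unit enrichment fold makes the target library look like IgG", {
  truth <- buildSyntheticGenome(smallScenario(7L, enrichmentFold = 1))
  top1 <- simulateCutrunFragments(truth, "TOP1", seed = 5L)
  igg <- simulateCutrunFragments(truth, "IgG", seed = 6L)
  hs <- truthHotspots(truth)
  inHot <- function(fs)
    sum(GenomicRanges::countOverlaps(midpointAnchors(fragments(fs)), hs) > 0)
  tab <- matrix(c(inHot(top1), length(fragments(top1)),
                  inHot(igg), length(fragments(igg))), nrow = 2)
  expect_gt(prop.test(tab[1, ], tab[2, ])$p.value, 0.01)
})

test_that("CAD-Seq libraries implement the seeded turnover model", {
  truth <- buildSyntheticGenome(smallScenario(8L))
  f1 <- simulateCadseqFragments(truth, "prolonged_30min", "control", seed = 4L)
  f2 <- simulateCadseqFragments(truth, "prolonged_30min", "control", seed = 4L)
  expect_identical(as.data.frame(fragments(f1)), as.data.frame(fragments(f2)))
  expect_identical(spikeInCount(f1), spikeInCount(f2))
  expect_error(simulateCadseqFragments(truth, "overnight", "control"))
  expect_error(simulateCadseqFragments(truth, "steady_5min", "wildtype"))

  # null scenario: delta 0 in both genotypes -> delta-TOP1cc ~ 0 everywhere
  tn <- buildSyntheticGenome(smallScenario(9L, deltaControl = 0, deltaKd = 0))
  d <- makeDeltaTrack(
    list(simulateCadseqFragments(tn, "prolonged_30min", "macroH2A1_1_KD", 1L)),
    list(simulateCadseqFragments(tn, "steady_5min", "macroH2A1_1_KD", 2L)),
    truthLayout(tn), 50L)
  hsMeans <- regionMeanSignal(d, truthHotspots(tn))
  expect_lt(abs(mean(hsMeans, na.rm = TRUE)), 0.1)
})

test_that("expected turnover is invariant to the steady-state rate", {
  reps <- function(lam) {
    sc <- smallScenario(11L, cadRatePerBp = lam)
    truth <- buildSyntheticGenome(sc)
    hs <- truthHotspots(truth)
    sel <- which(mcols(hs)$m == 1L & mcols(hs)$e > 0.5)
    vapply(1:3, function(s) {
      d <- makeDeltaTrack(
        list(simulateCadseqFragments(truth, "prolonged_30min",
                                     "macroH2A1_1_KD", seed = 100 + s)),
        list(simulateCadseqFragments(truth, "steady_5min", "macroH2A1_1_KD",
                                     seed = 200 + s)),
        truthLayout(truth), 10L)
      mean(regionMeanSignal(d, hs[sel]), na.rm = TRUE)
    }, numeric(1))
  }
  # same truth geometry (same seed); doubling lambda_s leaves the ratio
  # statistic unchanged up to Monte-Carlo noise
  expect_lt(abs(mean(reps(0.1)) - mean(reps(0.2))), 0.1)
})
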