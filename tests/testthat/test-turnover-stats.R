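mkGenes <- function(expr, chrom = "chr1", tssStep = 1000L) {
  n <- length(expr)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
             tss = seq_len(n) * tssStep, strand = "+", expression = expr)
}

test_that("expression quartiles are balanced with stable tie-breaks", {
  g <- assignExpressionQuartiles(mkGenes(1:8))
  expect_identical(as.character(g$quartile),
                   rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))

  tied <- assignExpressionQuartiles(mkGenes(rep(5, 8)))
  expect_identical(as.integer(table(tied$quartile)), rep(2L, 4))
  # stable order: earlier rows land in lower quartiles
  expect_identical(as.character(tied$quartile[1:2]), c("Q1", "Q1"))

  g10 <- assignExpressionQuartiles(mkGenes(10:1))
  sizes <- as.integer(table(g10$quartile))
  expect_identical(sum(sizes), 10L)
  expect_true(all(abs(sizes - 2.5) <= 0.5))
  # Q4 holds the top expressions (sizes 2,3,2,3 under the even-split rule)
  expect_true(min(g10$expression[g10$quartile == "Q4"]) >= 8)
  expect_lt(max(g10$expression[g10$quartile == "Q1"]),
            min(g10$expression[g10$quartile == "Q4"]))
  expect_error(assignExpressionQuartiles(mkGenes(1:3)), "at least 4")
})

test_that("Mann-Whitney U matches enumeration, symmetry and wilcox.test", {
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_identical(r$method, "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p, 1/3)

  # identical samples: p = 1 (symmetric, tie-corrected normal path)
  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  set.seed(9)
  for (case in 1:25) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    x <- sample(1000L, na + nb)  # distinct -> no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    mine <- mannWhitneyU(a, b)
    swap <- mannWhitneyU(b, a)
    expect_equal(swap$U, na * nb - mine$U)   # symmetry
    expect_equal(swap$p, mine$p)
    ref <- wilcox.test(a, b, exact = TRUE)   # independent implementation
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }

  # normal approximation with ties agrees with the reference
  set.seed(10)
  for (case in 1:10) {
    a <- sample(1:5, 20, replace = TRUE)
    b <- sample(2:6, 25, replace = TRUE)
    mine <- mannWhitneyU(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }

  # large shifted normals: decisively significant
  set.seed(11)
  big <- mannWhitneyU(rnorm(200), rnorm(200, mean = 1))
  expect_lt(big$p, 1e-6)
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("quartile stratification partitions genes and detects monotone effects", {
  n <- 40L
  gl <- tinyLayout(c(chr1 = 50000L))
  genes <- assignExpressionQuartiles(mkGenes(seq_len(n) / 4))
  # delta signal proportional to expression at each TSS
  v <- rep(0, 5000)
  for (i in seq_len(n)) {
    b <- (genes$tss[i] - 1) %/% 10 + 1
    v[(b - 30):(b + 30)] <- genes$expression[i] / 10
  }
  delta <- new("CoverageTrack", layout = gl, binSize = 10L,
               values = list(chr1 = v), normState = "log2_ratio")
  res <- deltaByGroup(delta, genes, windowHalfwidth = 250L)
  med <- stratSummary(res)$median
  expect_true(all(diff(med) > 0))
  expect_identical(sum(stratSummary(res)$n) + stratExcluded(res), n)
  expect_identical(nrow(stratTests(res)), 6L)  # all quartile pairs
  p41 <- stratTests(res)
  expect_lt(p41$p[p41$groupA == "Q1" & p41$groupB == "Q4"], 0.01)

  # all-zero ratio track: medians 0, equal groups give p = 1
  zero <- new("CoverageTrack", layout = gl, binSize = 10L,
              values = list(chr1 = rep(0, 5000)), normState = "log2_ratio")
  rz <- deltaByGroup(zero, genes)
  expect_true(all(stratSummary(rz)$median == 0))
  expect_true(all(stratTests(rz)$p == 1))

  # requires a ratio track
  raw <- rawTrack(list(chr1 = v), gl, 10L)
  expect_error(deltaByGroup(raw, genes), "log2_ratio")

  # fully-masked window (TSS 1) is excluded and counted
  vNA <- v; vNA[71:131] <- NA
  deltaNA <- new("CoverageTrack", layout = gl, binSize = 10L,
                 values = list(chr1 = vNA), normState = "log2_ratio")
  rNA <- deltaByGroup(deltaNA, genes)
  expect_identical(stratExcluded(rNA), 1L)
})

test_that("occupancy tertiles keep top and bottom thirds in stable order", {
  gl <- tinyLayout(c(chr1 = 9000L))
  peaks <- gr1(seq(1, 8001, by = 1000), seq(500, 8500, by = 1000))
  occ <- rawTrack(list(chr1 = rep(1:9, each = 100)), gl, 10L)
  tert <- stratifyBySignalTertiles(peaks, occ)
  expect_length(tert$high, 3L)
  expect_length(tert$low, 3L)
  expect_equal(sort(tert$scores[7:9]), sort(mcols(tert$high)$tertile_score))
  expect_true(all(start(tert$high) >= 6001))  # peaks scored 7,8,9
  expect_true(all(start(tert$low) <= 2001))   # peaks scored 1,2,3

  flat <- rawTrack(list(chr1 = rep(2, 900)), gl, 10L)
  expect_warning(t2 <- stratifyBySignalTertiles(peaks, flat), "equal")
  expect_identical(start(t2$low), start(peaks)[1:3])  # stable order
  expect_identical(start(t2$high), start(peaks)[7:9])
  expect_error(stratifyBySignalTertiles(peaks[1:2], occ), "at least 3")
})

test_that("tertile split by occupancy recovers true domain coverage", {
  truth <- buildSyntheticGenome(smallScenario(13L))
  fs <- simulateCutrunFragments(truth, "macroH2A1.1", seed = 4L)
  occ <- coverageFromFragments(fs, truthLayout(truth), 50L)
  tert <- stratifyBySignalTertiles(truthHotspots(truth), occ)
  fracCovered <- function(p)
    mean(GenomicRanges::countOverlaps(midpointAnchors(p),
                                      truthDomains(truth)) > 0)
  expect_gt(fracCovered(tert$high), fracCovered(tert$low))
})
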