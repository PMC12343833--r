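test_that("fragment binning equals per-base depth and conserves mass", {
  gl <- tinyLayout(c(chr1 = 1000L))
  tr <- coverageFromFragments(gr1(1, 100), gl, 50L)
  expect_equal(trackValues(tr)$chr1[1:3], c(1, 1, 0))
  expect_identical(normState(tr), "raw")

  tr <- coverageFromFragments(gr1(1, 75), gl, 50L)
  expect_equal(trackValues(tr)$chr1[1:2], c(1, 0.5))

  empty <- coverageFromFragments(GRanges(), gl, 50L)
  expect_true(all(unlist(trackValues(empty)) == 0))

  set.seed(11)
  for (case in 1:20) {
    gl <- tinyLayout(c(chr1 = 997L, chr2 = 600L))  # short last bin
    frags <- randomIntervals(gl, 25L, maxw = 120L)
    bs <- sample(c(7L, 10L, 50L), 1L)
    tr <- coverageFromFragments(frags, gl, bs)
    expect_equal(trackValues(tr), oracleCoverageBins(frags, gl, bs))
    # mass conservation: sum(value * binSize) == total fragment bp
    expect_equal(sum(unlist(trackValues(tr))) * bs, sum(width(frags)))
  }
})

test_that("spike-in scaling is linear and restricted to raw tracks", {
  gl <- tinyLayout()
  tr <- coverageFromFragments(gr1(c(1, 201), c(100, 400)), gl, 50L)
  same <- spikeInScale(tr, 10000L, 10000)
  expect_equal(trackValues(same), trackValues(tr))
  expect_identical(normState(same), "spike_scaled")

  half <- spikeInScale(tr, 20000L, 10000)
  expect_equal(unlist(trackValues(half)) * 2, unlist(trackValues(same)))

  expect_error(spikeInScale(tr, 0L), "spikeInCount")
  expect_error(spikeInScale(same, 100L), "raw track")
})

test_that("spike normalization removes sequencing-depth differences", {
  # same library chemistry sequenced at 1x and 2x depth: genomic and
  # spike-in reads both double, so spike-scaled tracks agree
  truth <- buildSyntheticGenome(smallScenario(5L))
  a <- simulateCutrunFragments(truth, "TOP1", seed = 8L)
  b <- simulateCutrunFragments(truth, "TOP1", seed = 9L,
                               nFragments = 2L * length(fragments(a)) +
                                 2L * spikeInCount(a))
  ta <- spikeInScale(coverageFromFragments(a, truthLayout(truth), 500L),
                     spikeInCount(a))
  tb <- spikeInScale(coverageFromFragments(b, truthLayout(truth), 500L),
                     spikeInCount(b))
  va <- unlist(trackValues(ta)); vb <- unlist(trackValues(tb))
  expect_equal(mean(vb) / mean(va), 1, tolerance = 0.1)
  expect_gt(cor(va, vb), 0.9)
})

test_that("Z-normalization matches the closed form with population SD", {
  gl <- tinyLayout(c(chr1 = 150L))
  tr <- rawTrack(list(chr1 = c(1, 2, 3)), gl, 50L)
  z <- znormalizeTrack(tr)
  expect_equal(trackValues(z)$chr1, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_identical(normState(z), "znormalized")

  set.seed(2)
  big <- rawTrack(list(chr1 = rlnorm(150)), tinyLayout(c(chr1 = 150L)), 1L)
  zb <- znormalizeTrack(big)
  v <- unlist(trackValues(zb))
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  # idempotence within float tolerance
  expect_equal(trackValues(znormalizeTrack(zb)), trackValues(zb),
               tolerance = 1e-12)

  expect_error(znormalizeTrack(rawTrack(list(chr1 = rep(2, 3)), gl, 50L)),
               "constant")
})

test_that("replicate combination averages tracks and merges fragment sets", {
  gl <- tinyLayout(c(chr1 = 100L))
  a <- rawTrack(list(chr1 = c(0, 4)), gl, 50L)
  b <- rawTrack(list(chr1 = c(2, 0)), gl, 50L)
  avg <- combineReplicates(list(a, b), "average_tracks")
  expect_equal(trackValues(avg)$chr1, c(1, 2))
  expect_equal(trackValues(combineReplicates(list(a, a), "average_tracks")),
               trackValues(a))

  other <- rawTrack(list(chr1 = c(0, 0, 0, 0)), gl, 25L)
  expect_error(combineReplicates(list(a, other), "average_tracks"),
               "bin size")
  expect_error(combineReplicates(list(a), "average_tracks"), "at least 2")
  sc <- spikeInScale(a, 100L)
  expect_error(combineReplicates(list(a, sc), "average_tracks"),
               "normalization state")

  f1 <- FragmentSet(randomIntervals(gl, 100L, 20L), 10L, "r1")
  f2 <- FragmentSet(randomIntervals(gl, 50L, 20L), 7L, "r2")
  m <- combineReplicates(list(f1, f2), "merge_fragments")
  expect_length(fragments(m), 150L)
  expect_identical(spikeInCount(m), 17L)
})

test_that("log2 ratio obeys identity, antisymmetry and the mask rule", {
  gl <- tinyLayout(c(chr1 = 200L))
  a <- rawTrack(list(chr1 = c(8, 0, 3, 100)), gl, 50L)
  b <- rawTrack(list(chr1 = c(8, 0, 5, 50)), gl, 50L)

  same <- log2RatioTrack(a, a, 0.5)
  v <- trackValues(same)$chr1
  expect_true(is.na(v[2]))        # 0/0 masked, not 0
  expect_true(all(v[-2] == 0))
  expect_identical(normState(same), "log2_ratio")

  ab <- trackValues(log2RatioTrack(a, b, 0.5))$chr1
  ba <- trackValues(log2RatioTrack(b, a, 0.5))$chr1
  expect_equal(ab[-2], -ba[-2])

  # values >> pseudocount: ratio of 2 gives ~1
  expect_equal(ab[4], 1, tolerance = 0.02)

  expect_error(log2RatioTrack(a, spikeInScale(b, 10L)), "state mismatch")
  expect_error(log2RatioTrack(a, b, pseudocount = 0), "pseudocount")
  expect_error(log2RatioTrack(znormalizeTrack(a), znormalizeTrack(b)),
               "raw or spike_scaled")
})

test_that("binned correlation honors rank invariance and sign", {
  set.seed(4)
  gl <- tinyLayout(c(chr1 = 10000L))
  v <- rlnorm(100)
  a <- rawTrack(list(chr1 = v), gl, 100L)
  cube <- rawTrack(list(chr1 = v^3), gl, 100L)
  neg <- rawTrack(list(chr1 = -v), gl, 100L)
  m <- binnedCorrelation(list(a = a, cube = cube, neg = neg),
                         windowSize = 100L, method = "spearman")
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_equal(m["a", "cube"], 1)
  expect_equal(m["a", "neg"], -1)
  expect_equal(m, t(m))
  expect_error(binnedCorrelation(list(a)), "at least 2")
})
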