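test_that("signal matrices respect constants, strand flips and edge padding", {
  gl <- tinyLayout(c(chr1 = 1000L))
  const <- rawTrack(list(chr1 = rep(3.5, 100)), gl, 10L)
  anch <- gr1(500, 500, strand = "*")
  m <- signalValues(computeSignalMatrix(const, anch, 100L, 100L, 10L))
  expect_true(all(m == 3.5))

  # signal only right of the anchor: plus-strand row -> right half;
  # minus-strand -> left half after orientation flip
  v <- rep(0, 100); v[52:100] <- 1  # bases 511..1000
  step <- rawTrack(list(chr1 = v), gl, 10L)
  plus <- signalValues(computeSignalMatrix(
    step, gr1(501, 501, strand = "+"), 100L, 100L, 10L))[1, ]
  minus <- signalValues(computeSignalMatrix(
    step, gr1(501, 501, strand = "-"), 100L, 100L, 10L))[1, ]
  expect_true(all(plus[1:10] == 0) && all(plus[12:20] == 1))
  expect_true(all(minus[11:20] == 0) && all(minus[1:9] == 1))

  # window past the chromosome start: leading columns missing, not zero
  pad <- signalValues(computeSignalMatrix(const, gr1(100, 100), 500L, 500L,
                                          100L))[1, ]
  expect_true(all(is.na(pad[1:4])))
  expect_true(all(pad[5:10] == 3.5))

  expect_error(computeSignalMatrix(const, gr1(10, 10, chrom = "chrZ"),
                                   100L, 100L, 10L), "unknown chromosome")
  expect_error(computeSignalMatrix(const, anch, 95L, 100L, 10L), "divide")
})

test_that("mirroring track and strand leaves matrix rows unchanged", {
  set.seed(21)
  for (case in 1:10) {
    L <- 1000L; bs <- 10L
    gl <- tinyLayout(c(chr1 = L))
    v <- runif(L / bs)
    fwd <- rawTrack(list(chr1 = v), gl, bs)
    rev <- rawTrack(list(chr1 = base::rev(v)), gl, bs)
    p <- sample(300:700, 1L)
    rowF <- signalValues(computeSignalMatrix(
      fwd, gr1(p, p, strand = "+"), 100L, 200L, 10L))[1, ]
    # mirror base x -> L + 1 - x maps the anchor and flips orientation
    rowR <- signalValues(computeSignalMatrix(
      rev, gr1(L + 1L - p, L + 1L - p, strand = "-"), 100L, 200L, 10L))[1, ]
    expect_equal(rowF, rowR, tolerance = 1e-12)
  }
})

test_that("mean profiles average columns and LOESS preserves lines", {
  gl <- tinyLayout(c(chr1 = 1000L))
  v <- seq(0.1, 10, length.out = 100)
  tr <- rawTrack(list(chr1 = v), gl, 10L)
  anch <- gr1(c(500, 500), c(500, 500))
  m <- computeSignalMatrix(tr, anch, 100L, 100L, 10L)
  prof <- meanProfile(m)
  expect_equal(prof$mean, colMeans(signalValues(m)))  # brute-force col mean
  expect_true(all(prof$n == 2L))

  # identical rows -> profile equals the row; exact line is reproduced by
  # degree-1 LOESS
  sm <- meanProfile(m, span = 0.3)
  expect_equal(sm$smoothed, sm$mean, tolerance = 1e-6)

  # two-row {0-row, 2-row} matrix -> all-1 profile
  z <- rawTrack(list(chr1 = rep(0, 100)), gl, 10L)
  two <- rawTrack(list(chr1 = rep(2, 100)), gl, 10L)
  mz <- signalValues(computeSignalMatrix(z, gr1(500, 500), 100L, 100L, 10L))
  mt <- signalValues(computeSignalMatrix(two, gr1(500, 500), 100L, 100L, 10L))
  both <- new("SignalMatrix", values = rbind(mz, mt), upstream = 100L,
              downstream = 100L, binWidth = 10L,
              anchors = data.frame(chrom = c("chr1", "chr1"),
                                   position = c(500, 500),
                                   strand = c("*", "*")),
              trackLabel = "t")
  expect_true(all(meanProfile(both)$mean == 1))
})

test_that("LOESS at span 1 approaches the global linear fit and is equivariant", {
  set.seed(1)
  n <- 60L
  gl <- tinyLayout(c(chr1 = 10000L))
  noise <- 0.5 * seq_len(n) + rnorm(n, sd = 2)
  mk <- function(y) new("SignalMatrix", values = matrix(y, 1), upstream = 300L,
                        downstream = 300L, binWidth = 10L,
                        anchors = data.frame(chrom = "chr1", position = 5000,
                                             strand = "*"), trackLabel = "t")
  prof <- meanProfile(mk(noise), span = 1)
  ols <- fitted(lm(noise ~ prof$offset))
  expect_lt(max(abs(prof$smoothed - ols)), 0.5)

  # shift equivariance and homogeneity
  base <- meanProfile(mk(noise), span = 0.25)$smoothed
  shifted <- meanProfile(mk(noise + 7), span = 0.25)$smoothed
  scaled <- meanProfile(mk(noise * 3), span = 0.25)$smoothed
  expect_equal(shifted, base + 7, tolerance = 1e-8)
  expect_equal(scaled, base * 3, tolerance = 1e-8)
})

test_that("region means weight partial bins and flag missing windows", {
  gl <- tinyLayout(c(chr1 = 100L))
  tr <- rawTrack(list(chr1 = c(4, 8)), gl, 50L)
  # 0-based [25,75) = 1-based [26,75]: halves of each bin -> 6.0
  expect_equal(regionMeanSignal(tr, gr1(26, 75)), 6)
  const <- rawTrack(list(chr1 = rep(2.2, 2)), gl, 50L)
  expect_equal(regionMeanSignal(const, gr1(c(1, 30), c(10, 90))), c(2.2, 2.2))

  masked <- rawTrack(list(chr1 = c(NA, 8)), gl, 50L)
  expect_true(is.na(regionMeanSignal(masked, gr1(1, 50))))
  expect_equal(regionMeanSignal(masked, gr1(26, 75)), 8)  # NA excluded

  set.seed(33)
  for (case in 1:20) {
    gl2 <- tinyLayout(c(chr1 = 777L, chr2 = 500L))
    bs <- sample(c(9L, 25L, 50L), 1L)
    vals <- lapply(chromLengths(gl2), function(L) {
      v <- runif(ceiling(L / bs)); v[sample(length(v), 2L)] <- NA; v
    })
    tr2 <- rawTrack(vals, gl2, bs)
    w <- randomIntervals(gl2, 15L, maxw = 200L)
    expect_equal(regionMeanSignal(tr2, w), oracleRegionMeans(tr2, w))
  }
})
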