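# Per-base brute-force oracles and small fixture builders. Oracles work on
# plain vectors over tiny (<= 10 kb) genomes and never share code with the
# implementation they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr1 <- function(starts, ends, chrom = "chr1", strand = "*")
  GRanges(chrom, IRanges(starts, ends), strand = strand)

tinyLayout <- function(lengths = c(chr1 = 1000L), blacklist = NULL)
  GenomeLayout(names(lengths), lengths, blacklist = blacklist)

# random interval set within a layout (1-based closed), widths <= maxw
randomIntervals <- function(layout, n, maxw = 100L) {
  ln <- chromLengths(layout)
  ch <- sample(names(ln), n, replace = TRUE)
  w <- sample.int(maxw, n, replace = TRUE)
  w <- pmin(w, ln[ch])
  s <- vapply(seq_len(n), function(i)
    sample.int(ln[[ch[i]]] - w[i] + 1L, 1L), integer(1))
  GRanges(ch, IRanges(s, s + w - 1L))
}

# per-chromosome base membership bitmap of an interval set
baseBitmap <- function(gr, layout) {
  ln <- chromLengths(layout)
  out <- lapply(names(ln), function(ch) {
    v <- logical(ln[[ch]])
    g <- gr[as.character(seqnames(gr)) == ch]
    for (i in seq_along(g)) v[start(g)[i]:end(g)[i]] <- TRUE
    v
  })
  names(out) <- names(ln)
  out
}

oracleJaccard <- function(a, b, layout) {
  ba <- unlist(baseBitmap(a, layout))
  bb <- unlist(baseBitmap(b, layout))
  sum(ba & bb) / sum(ba | bb)
}

oracleCoverageBins <- function(frags, layout, bs) {
  ln <- chromLengths(layout)
  out <- lapply(names(ln), function(ch) {
    depth <- integer(ln[[ch]])
    g <- frags[as.character(seqnames(frags)) == ch]
    for (i in seq_along(g)) {
      idx <- start(g)[i]:end(g)[i]
      depth[idx] <- depth[idx] + 1L
    }
    nb <- ceiling(ln[[ch]] / bs)
    vapply(seq_len(nb), function(b) {
      sum(depth[((b - 1L) * bs + 1L):min(b * bs, ln[[ch]])]) / bs
    }, numeric(1))
  })
  names(out) <- names(ln)
  out
}

# per-base expansion of a binned track (NA bins expand to NA)
oracleRegionMeans <- function(track, windows) {
  ln <- chromLengths(trackLayout(track))
  bs <- binSize(track)
  perBase <- lapply(names(ln), function(ch) {
    rep(trackValues(track)[[ch]], each = bs)[seq_len(ln[[ch]])]
  })
  names(perBase) <- names(ln)
  vapply(seq_along(windows), function(i) {
    ch <- as.character(seqnames(windows))[i]
    v <- perBase[[ch]][start(windows)[i]:end(windows)[i]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

oracleBlacklistKeep <- function(gr, layout) {
  bl <- baseBitmap(blacklist(layout), layout)
  vapply(seq_along(gr), function(i) {
    ch <- as.character(seqnames(gr))[i]
    !any(bl[[ch]][start(gr)[i]:end(gr)[i]])
  }, logical(1))
}

rawTrack <- function(values, layout, bs) {
  new("CoverageTrack", layout = layout, binSize = as.integer(bs),
      values = values, normState = "raw")
}

# small scenario used where full default size is unnecessary
smallScenario <- function(seed = 1L, ...)
  simScenario(chromLengths = c(chr1 = 5e5, chr2 = 5e5), nGenes = 80L,
              nHotspots = 60L, nDomains = 40L, rngSeed = as.integer(seed), ...)
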