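# ---- internal numeric core (0-based half-open, genome-linearized) ----------
# Chromosomes are laid out on one number line with a 1-bp guard gap so that
# intervals on different chromosomes can never merge or intersect.

.chromOffsets <- function(lengths) {
  off <- cumsum(c(0, utils::head(as.numeric(lengths) + 1, -1L)))
  names(off) <- names(lengths)
  off
}

.linearize <- function(gr, offsets) {
  o <- offsets[as.character(seqnames(gr))]
  list(s = o + start(gr) - 1, e = o + end(gr))
}

.flatten0 <- function(s, e) {
  n <- length(s)
  if (!n) return(list(s = numeric(0), e = numeric(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  cme <- cummax(e)
  new <- c(TRUE, s[-1L] > cme[-n])  # s == previous end => abutting => merge
  list(s = s[new], e = cme[c(which(new)[-1L] - 1L, n)])
}

.coveredBp <- function(f) sum(f$e - f$s)

.membership <- function(ps, f) {
  if (!length(f$s)) return(rep(FALSE, length(ps)))
  i <- findInterval(ps, f$s)
  ok <- i >= 1L
  ok & ps < f$e[ifelse(ok, i, 1L)]
}

.intersectBp <- function(fa, fb) {
  if (!length(fa$s) || !length(fb$s)) return(0)
  pts <- sort(unique(c(fa$s, fa$e, fb$s, fb$e)))
  ps <- pts[-length(pts)]
  w <- diff(pts)
  sum(w[.membership(ps, fa) & .membership(ps, fb)])
}

.jaccard0 <- function(fa, fb) {
  inter <- .intersectBp(fa, fb)
  uni <- .coveredBp(fa) + .coveredBp(fb) - inter
  if (uni == 0) stop("Jaccard undefined: both interval sets are empty")
  inter / uni
}

# Random relocation of intervals of widths w. Returns chrom index + 0-based
# start. Chromosomes weighted by their number of valid start positions.
.shuffleCore <- function(w, lengths, offsets, blFlat, sameChrom = FALSE,
                         origChrom = NULL, maxRounds = 100L) {
  n <- length(w)
  nch <- length(lengths)
  L <- as.numeric(lengths)
  draw <- function(idx) {
    wi <- w[idx]
    m <- length(idx)
    if (sameChrom) {
      ci <- origChrom[idx]
      nv <- L[ci] - wi + 1
      if (any(nv <= 0))
        stop("interval ", idx[which(nv <= 0)[1L]],
             " is longer than its chromosome")
      st <- floor(stats::runif(m) * nv)
    } else {
      nv <- outer(L, wi, function(l, ww) pmax(0, l - ww + 1))  # nch x m
      tot <- colSums(nv)
      if (any(tot <= 0))
        stop("interval ", idx[which(tot <= 0)[1L]],
             " is longer than every chromosome")
      u <- stats::runif(m) * tot
      cum <- apply(nv, 2L, cumsum)
      if (is.null(dim(cum))) cum <- matrix(cum, nrow = nch)
      ci <- colSums(cum < rep(u, each = nch)) + 1L
      before <- cum[cbind(ci, seq_len(m))] - nv[cbind(ci, seq_len(m))]
      st <- floor(u - before)
      st <- pmin(st, L[ci] - wi)  # guard against floating-point edge
    }
    list(ci = ci, st = st)
  }
  ci <- integer(n); st <- numeric(n)
  todo <- seq_len(n)
  for (round in seq_len(maxRounds)) {
    d <- draw(todo)
    ci[todo] <- d$ci; st[todo] <- d$st
    if (!length(blFlat$s)) { todo <- integer(0); break }
    ls <- offsets[ci[todo]] + st[todo]
    le <- ls + w[todo]
    # overlap with blacklist: left neighbour reaches in, or a blacklist start
    # falls inside the interval
    i <- findInterval(ls, blFlat$s)
    hitL <- i >= 1L & ls < blFlat$e[ifelse(i >= 1L, i, 1L)]
    hitR <- findInterval(le - 0.5, blFlat$s) > i
    bad <- hitL | hitR
    todo <- todo[bad]
    if (!length(todo)) break
  }
  if (length(todo))
    stop("could not place interval ", todo[1L], " (width ", w[todo[1L]],
         ") outside the blacklist after ", maxRounds, " rounds")
  list(ci = ci, st = st)
}

# ---- exported operations ----------------------------------------------------

#' Flatten an interval set
#'
#' Merges overlapping and abutting intervals so that union/intersection sizes
#' in bp are well defined; total covered bp is preserved and the output is
#' sorted. Strand is ignored.
#'
#' @param gr a `GRanges`.
#' @return a sorted, disjoint, unstranded `GRanges`.
#' @export
flattenIntervals <- function(gr) {
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Base-pair Jaccard index of two interval sets
#'
#' Bases in the intersection divided by bases in the union, bounded by 0 (no
#' overlap) and 1 (complete overlap). Both sets are flattened internally.
#' Two empty sets are an error (0/0 is undefined), not 0.
#'
#' @param a,b `GRanges` interval sets on the same chromosome namespace.
#' @return the Jaccard index in [0, 1].
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 15))
#' jaccardIndex(a, b)  # 5 / 15
#' @export
jaccardIndex <- function(a, b) {
  chs <- unique(c(as.character(seqnames(a)), as.character(seqnames(b))))
  if (!length(chs)) stop("Jaccard undefined: both interval sets are empty")
  span <- vapply(chs, function(ch) {
    m <- c(end(a)[as.character(seqnames(a)) == ch],
           end(b)[as.character(seqnames(b)) == ch], 0)
    max(m)
  }, numeric(1))
  off <- .chromOffsets(span)
  .jaccard0(do.call(.flatten0, .linearize(a, off)),
            do.call(.flatten0, .linearize(b, off)))
}

#' Randomly relocate intervals within genome bounds
#'
#' Places each interval uniformly at random among all valid start positions,
#' across chromosomes weighted by their number of valid starts (or on the
#' interval's own chromosome when `sameChrom = TRUE`). Interval lengths are
#' preserved as a multiset. Placements overlapping the layout's blacklist
#' are redrawn (rejection); shuffled intervals may overlap one another,
#' mirroring the default of the standard interval-shuffling tool.
#'
#' @param gr a `GRanges` to relocate.
#' @param layout the governing [GenomeLayout-class] (bounds + blacklist).
#' @param seed optional integer seed; when given, the R RNG is seeded for a
#'   reproducible shuffle.
#' @param sameChrom keep each interval on its own chromosome.
#' @param maxRounds rejection rounds before giving up (error naming the
#'   interval).
#' @return an unstranded `GRanges` of relocated intervals, input order.
#' @export
shuffleIntervals <- function(gr, layout, seed = NULL, sameChrom = FALSE,
                             maxRounds = 100L) {
  stopifnot(is(layout, "GenomeLayout"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!length(gr)) return(GRanges(seqinfo = layout@seqinfo))
  ln <- chromLengths(layout)
  off <- .chromOffsets(ln)
  blFlat <- do.call(.flatten0, .linearize(blacklist(layout), off))
  origChrom <- match(as.character(seqnames(gr)), names(ln))
  if (sameChrom && anyNA(origChrom))
    stop("interval on chromosome absent from layout")
  d <- .shuffleCore(as.numeric(width(gr)), ln, off, blFlat,
                    sameChrom = sameChrom, origChrom = origChrom,
                    maxRounds = maxRounds)
  GRanges(names(ln)[d$ci], IRanges(start = d$st + 1L, width = width(gr)),
          seqinfo = layout@seqinfo)
}

#' Permutation test of interval-set colocalization
#'
#' Compares the observed Jaccard index of two interval sets against a null
#' distribution obtained by independently relocating the intervals of both
#' sets (or only the second, with `shuffleBoth = FALSE`) uniformly within
#' genome bounds, avoiding the blacklist. The empirical p value uses the
#' add-one estimator `(1 + #(null >= observed)) / (nShuffles + 1)` so it is
#' never zero.
#'
#' @param a,b `GRanges` interval sets.
#' @param layout the governing [GenomeLayout-class].
#' @param nShuffles number of permutations (default 1000).
#' @param seed optional integer seed, recorded in the result.
#' @param shuffleBoth shuffle both sets per iteration (default `TRUE`).
#' @param maxRounds blacklist-rejection rounds per shuffle.
#' @return a [JaccardResult-class].
#' @export
permutationColocalization <- function(a, b, layout, nShuffles = 1000L,
                                      seed = NULL, shuffleBoth = TRUE,
                                      maxRounds = 100L) {
  stopifnot(is(layout, "GenomeLayout"))
  nShuffles <- as.integer(nShuffles)
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ln <- chromLengths(layout)
  off <- .chromOffsets(ln)
  blFlat <- do.call(.flatten0, .linearize(blacklist(layout), off))
  aLin <- .linearize(a, off); bLin <- .linearize(b, off)
  observed <- .jaccard0(do.call(.flatten0, aLin), do.call(.flatten0, bLin))
  wa <- as.numeric(width(a)); wb <- as.numeric(width(b))
  bFlat0 <- do.call(.flatten0, bLin)
  nullValues <- numeric(nShuffles)
  for (i in seq_len(nShuffles)) {
    da <- .shuffleCore(wa, ln, off, blFlat, maxRounds = maxRounds)
    fa <- .flatten0(off[da$ci] + da$st, off[da$ci] + da$st + wa)
    if (shuffleBoth) {
      db <- .shuffleCore(wb, ln, off, blFlat, maxRounds = maxRounds)
      fb <- .flatten0(off[db$ci] + db$st, off[db$ci] + db$st + wb)
    } else {
      fb <- bFlat0
    }
    nullValues[i] <- .jaccard0(fa, fb)
  }
  empiricalP <- (1 + sum(nullValues >= observed)) / (nShuffles + 1)
  sdNull <- stats::sd(nullValues)
  z <- if (is.na(sdNull) || sdNull == 0) NA_real_ else
    (observed - mean(nullValues)) / sdNull
  new("JaccardResult", observed = observed, nullValues = nullValues,
      empiricalP = empiricalP, zScore = z, nShuffles = nShuffles,
      seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' Classify peaks by TSS proximity
#'
#' Distance is measured from the peak midpoint to the nearest TSS. Peaks
#' within 3 kb are TSS-proximal; peaks more than 10 kb away are TSS-distal;
#' peaks in the 3-10 kb gap are excluded. The partition is exhaustive and
#' disjoint.
#'
#' @param peaks a `GRanges` of peaks.
#' @param genes non-empty gene table (columns `chrom`, `tss`).
#' @param proximalMax maximum midpoint-to-TSS distance of a proximal peak
#'   (default 3000 bp, inclusive).
#' @param distalMin distance beyond which a peak is distal (default 10000
#'   bp, exclusive: exactly 10 kb is still excluded).
#' @return list of `GRanges`: `proximal`, `distal`, `excluded`, plus the
#'   numeric `distance` per input peak.
#' @export
classifyTssProximity <- function(peaks, genes, proximalMax = 3000,
                                 distalMin = 10000) {
  if (!nrow(genes)) stop("gene table is empty")
  mid <- floor((start(peaks) + end(peaks)) / 2)
  chs <- as.character(seqnames(peaks))
  dist <- rep(Inf, length(peaks))
  for (ch in unique(chs)) {
    tss <- genes$tss[genes$chrom == ch]
    idx <- which(chs == ch)
    if (length(tss))
      dist[idx] <- vapply(mid[idx], function(m) min(abs(m - tss)), numeric(1))
  }
  prox <- dist <= proximalMax
  distal <- dist > distalMin
  list(proximal = peaks[prox], distal = peaks[distal],
       excluded = peaks[!prox & !distal], distance = dist)
}

#' Components of a JaccardResult
#' @param x a [JaccardResult-class].
#' @return `jaccardObserved`: observed index; `jaccardNull`: permuted null
#'   values; `jaccardP`: add-one empirical p; `jaccardZ`: z-score.
#' @name jaccard-accessors
NULL

#' @rdname jaccard-accessors
#' @export
jaccardObserved <- function(x) { stopifnot(is(x, "JaccardResult")); x@observed }
#' @rdname jaccard-accessors
#' @export
jaccardNull <- function(x) { stopifnot(is(x, "JaccardResult")); x@nullValues }
#' @rdname jaccard-accessors
#' @export
jaccardP <- function(x) { stopifnot(is(x, "JaccardResult")); x@empiricalP }
#' @rdname jaccard-accessors
#' @export
jaccardZ <- function(x) { stopifnot(is(x, "JaccardResult")); x@zScore }
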