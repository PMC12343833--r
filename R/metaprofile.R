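# Internal: bp-weighted window sums over a binned track via prefix integrals.
# F(x) = integral of the per-base track value over bases 1..x (NA bins
# contribute 0); D(x) = defined bp through x. A window mean is then
# (F(e) - F(s-1)) / (D(e) - D(s-1)), NA when no defined bp. Out-of-bounds
# portions of a window contribute no defined bp (missing, not zero).
.chromPrefix <- function(vals, bs, L) {
  nb <- length(vals)
  widths <- rep(bs, nb)
  if (nb) widths[nb] <- L - (nb - 1L) * bs
  def <- !is.na(vals)
  v0 <- ifelse(def, vals, 0)
  list(cumV = c(0, cumsum(v0 * widths)), cumD = c(0, cumsum(def * widths)),
       v0 = v0, def = def, bs = bs, L = L, nb = nb)
}

.prefixEval <- function(pf, x) {
  x <- pmax(0, pmin(x, pf$L))
  b <- pmin(pmax(ceiling(x / pf$bs), 1L), pf$nb)
  within <- x - (b - 1L) * pf$bs
  Fx <- pf$cumV[b] + pf$v0[b] * within
  Dx <- pf$cumD[b] + pf$def[b] * within
  Fx[x == 0] <- 0; Dx[x == 0] <- 0
  list(F = Fx, D = Dx)
}

# Window means over one chromosome; starts/ends 1-based closed, may exceed
# bounds (out-of-bounds bp counted as undefined).
.windowMeans <- function(pf, starts, ends) {
  hi <- .prefixEval(pf, ends)
  lo <- .prefixEval(pf, starts - 1)
  d <- hi$D - lo$D
  out <- (hi$F - lo$F) / d
  out[d == 0] <- NA_real_
  out
}

.trackPrefixes <- function(track) {
  ln <- chromLengths(trackLayout(track))
  bs <- binSize(track)
  pfs <- lapply(names(ln), function(ch)
    .chromPrefix(trackValues(track)[[ch]], bs, ln[[ch]]))
  names(pfs) <- names(ln)
  pfs
}

#' Reference-point signal matrix
#'
#' Computes, for each anchor point, the mean track signal in positional bins
#' spanning `[-upstream, +downstream)` around the anchor — the
#' reference-point mode of deepTools' computeMatrix. Rows of minus-strand
#' anchors are orientation-flipped so that column 1 is always the 5'-most
#' position relative to the anchor. Windows extending past chromosome ends
#' yield `NA` cells (missing, never zero-filled).
#'
#' @param track a [CoverageTrack-class].
#' @param anchors a width-1 `GRanges` of anchor points (strand `+`, `-` or
#'   `*`), or a [SimTruth-class] gene table converted via [tssAnchors()].
#' @param upstream,downstream flank sizes in bp; both must be multiples of
#'   `binWidth`.
#' @param binWidth positional bin width in bp.
#' @return a [SignalMatrix-class].
#' @seealso [meanProfile()]
#' @export
computeSignalMatrix <- function(track, anchors, upstream = 3000L,
                                downstream = 3000L, binWidth = 10L) {
  stopifnot(is(track, "CoverageTrack"), is(anchors, "GRanges"))
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  binWidth <- as.integer(binWidth)
  if (upstream %% binWidth != 0L || downstream %% binWidth != 0L)
    stop("binWidth must divide upstream and downstream")
  if (any(width(anchors) != 1L))
    stop("anchors must be width-1 points; use tssAnchors()/midpointAnchors()")
  ln <- chromLengths(trackLayout(track))
  chs <- as.character(seqnames(anchors))
  if (!all(chs %in% names(ln)))
    stop("anchor on unknown chromosome: ", setdiff(chs, names(ln))[1L])
  nc <- (upstream + downstream) %/% binWidth
  n <- length(anchors)
  mat <- matrix(NA_real_, n, nc)
  pfs <- .trackPrefixes(track)
  pos <- start(anchors)
  str <- as.character(strand(anchors))
  # signed 5'->3' offsets of cell j: [ -upstream + (j-1)*bw, -upstream + j*bw )
  off1 <- -upstream + (seq_len(nc) - 1L) * binWidth
  off2 <- off1 + binWidth
  for (ch in unique(chs)) {
    idx <- which(chs == ch)
    pf <- pfs[[ch]]
    for (i in idx) {
      if (str[i] == "-") {
        # reversed orientation: offset o maps to genomic position pos - o
        gs <- pos[i] - off2 + 1L
        ge <- pos[i] - off1
      } else {
        gs <- pos[i] + off1
        ge <- pos[i] + off2 - 1L
      }
      mat[i, ] <- .windowMeans(pf, gs, ge)
    }
  }
  new("SignalMatrix", values = mat, upstream = upstream,
      downstream = downstream, binWidth = binWidth,
      anchors = data.frame(chrom = chs, position = pos, strand = str),
      trackLabel = "track")
}

#' Matrix values of a SignalMatrix
#' @param x a [SignalMatrix-class].
#' @return the numeric anchors-x-bins matrix.
#' @export
signalValues <- function(x) {
  stopifnot(is(x, "SignalMatrix"))
  x@values
}

#' Column-mean profile with optional LOESS smoothing
#'
#' Averages a [SignalMatrix-class] column-wise over non-missing cells and
#' optionally smooths the profile with LOESS: degree-1 local regression with
#' tricube weights over the nearest `ceiling(span * ncol)` columns, no
#' robustness iterations. Smoothing an exactly linear profile returns it
#' unchanged. Output length equals the column count.
#'
#' @param mat a [SignalMatrix-class].
#' @param span LOESS span in (0, 1], or `NULL` for no smoothing.
#' @return data.frame with columns `offset` (bin-center offset from the
#'   anchor, bp, 5'->3'), `n` (non-missing cells), `mean` (raw column mean)
#'   and, when `span` is given, `smoothed`.
#' @export
meanProfile <- function(mat, span = NULL) {
  stopifnot(is(mat, "SignalMatrix"))
  v <- mat@values
  if (!nrow(v)) stop("empty signal matrix")
  n <- colSums(!is.na(v))
  mu <- colMeans(v, na.rm = TRUE)
  mu[n == 0L] <- NA_real_
  nc <- ncol(v)
  offset <- -mat@upstream + (seq_len(nc) - 0.5) * mat@binWidth
  out <- data.frame(offset = offset, n = n, mean = mu)
  if (!is.null(span)) {
    if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
    ok <- !is.na(mu)
    if (sum(ok) >= 4L) {
      fit <- stats::loess(mu[ok] ~ offset[ok], span = span, degree = 1,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      sm <- rep(NA_real_, nc)
      sm[ok] <- stats::predict(fit, newdata = offset[ok])
      out$smoothed <- sm
    } else {
      out$smoothed <- mu
    }
  }
  out
}

#' Mean track signal per region
#'
#' One value per window: the bp-weighted mean of the track over the window,
#' spreading partial bins proportionally. Missing bins are excluded from the
#' mean; windows with no defined bp yield `NA`.
#'
#' @param track a [CoverageTrack-class].
#' @param windows a `GRanges` of windows (validated against the track layout).
#' @return numeric vector, one value per window (`NA` = fully missing).
#' @export
regionMeanSignal <- function(track, windows) {
  stopifnot(is(track, "CoverageTrack"), is(windows, "GRanges"))
  ln <- chromLengths(trackLayout(track))
  chs <- as.character(seqnames(windows))
  if (!all(chs %in% names(ln)))
    stop("window on unknown chromosome: ", setdiff(chs, names(ln))[1L])
  out <- rep(NA_real_, length(windows))
  pfs <- .trackPrefixes(track)
  for (ch in unique(chs)) {
    idx <- which(chs == ch)
    out[idx] <- .windowMeans(pfs[[ch]], start(windows)[idx], end(windows)[idx])
  }
  out
}

#' TSS anchor points of a gene table
#'
#' @param genes gene table data.frame with columns `gene_id`, `chrom`, `tss`
#'   (1-based position), `strand`, `expression`.
#' @param layout optional [GenomeLayout-class] supplying seqinfo.
#' @return a width-1 stranded `GRanges`, one point per gene, in table order.
#' @export
tssAnchors <- function(genes, layout = NULL) {
  gr <- GRanges(genes$chrom, IRanges(genes$tss, width = 1L),
                strand = genes$strand)
  if (!is.null(layout))
    gr <- GRanges(seqnames(gr), IRanges(start(gr), width = 1L),
                  strand = strand(gr), seqinfo = layout@seqinfo)
  mcols(gr)$gene_id <- genes$gene_id
  gr
}

#' Midpoint anchors of an interval set
#'
#' @param gr a `GRanges` of intervals (e.g. peaks). Anchors are treated as
#'   unstranded, matching the convention for TSS-distal peaks.
#' @return a width-1 unstranded `GRanges` at the interval midpoints.
#' @export
midpointAnchors <- function(gr) {
  mid <- floor((start(gr) + end(gr)) / 2)
  out <- GRanges(seqnames(gr), IRanges(mid, width = 1L),
                 seqinfo = GenomeInfoDb::seqinfo(gr))
  mcols(out) <- mcols(gr)
  out
}
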