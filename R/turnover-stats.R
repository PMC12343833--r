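#' Assign gene-expression quartiles
#'
#' Ranks genes by expression (ties broken by stable table order) and splits
#' the ranks into four groups as evenly as possible (sizes differ by at most
#' one). Q1 is the bottom 25% of expression, Q4 the top 25%.
#'
#' @param genes gene table data.frame with an `expression` column.
#' @return the gene table with a `quartile` factor column (`Q1`...`Q4`).
#' @export
assignExpressionQuartiles <- function(genes) {
  n <- nrow(genes)
  if (n < 4L) stop("need at least 4 genes for quartiles")
  if (any(!is.finite(genes$expression))) stop("expression must be finite")
  ord <- order(genes$expression, seq_len(n))  # stable tie-break
  bounds <- floor(n * (0:4) / 4)
  qt <- integer(n)
  for (q in 1:4) qt[ord[(bounds[q] + 1L):bounds[q + 1L]]] <- q
  genes$quartile <- factor(paste0("Q", qt), levels = paste0("Q", 1:4))
  genes
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p by full enumeration of all rank assignments when the pooled
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. U is counted
#' for the first sample (number of (a, b) pairs with a > b, ties half).
#'
#' @param a,b non-empty numeric samples.
#' @return list with elements `U`, `p` (two-sided), and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
mannWhitneyU <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (n <= 12L && !ties) {
    comb <- utils::combn(n, na)
    Us <- colSums(matrix(seq_len(n)[comb], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  tab <- table(c(a, b))
  tieTerm <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tieTerm)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  if (U == mu) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal")
}

.pairwiseMWU <- function(groups, adjust = FALSE) {
  labs <- names(groups)
  combs <- utils::combn(length(labs), 2L)
  res <- data.frame(groupA = labs[combs[1L, ]], groupB = labs[combs[2L, ]],
                    U = NA_real_, p = NA_real_)
  for (k in seq_len(ncol(combs))) {
    ga <- groups[[combs[1L, k]]]; gb <- groups[[combs[2L, k]]]
    if (length(ga) && length(gb)) {
      t <- mannWhitneyU(ga, gb)
      res$U[k] <- t$U; res$p[k] <- t$p
    }
  }
  if (adjust) res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res
}

.groupSummary <- function(groups) {
  data.frame(group = names(groups),
             n = vapply(groups, length, integer(1)),
             median = vapply(groups, function(g)
               if (length(g)) stats::median(g) else NA_real_, numeric(1)),
             q1 = vapply(groups, function(g)
               if (length(g)) unname(stats::quantile(g, 0.25)) else NA_real_,
               numeric(1)),
             q3 = vapply(groups, function(g)
               if (length(g)) unname(stats::quantile(g, 0.75)) else NA_real_,
               numeric(1)),
             row.names = NULL)
}

#' Turnover signal by expression quartile
#'
#' Computes the per-gene mean delta-TOP1cc signal over TSS +/- a half-width
#' window (default 250 bp), groups genes by expression quartile and runs all
#' six pairwise two-sided Mann-Whitney U tests between quartiles. Genes with
#' fully-missing windows are excluded and counted.
#'
#' @param deltaTrack a `log2_ratio` [CoverageTrack-class] (delta-TOP1cc).
#' @param genes gene table with assigned quartiles (see
#'   [assignExpressionQuartiles()]).
#' @param windowHalfwidth half-width of the TSS window in bp (default 250).
#' @param adjust also report Benjamini-Hochberg adjusted p values
#'   (default `FALSE`; the pairwise tests are reported raw).
#' @return a [StratifiedResult-class] with groups `Q1`...`Q4`.
#' @export
deltaByGroup <- function(deltaTrack, genes, windowHalfwidth = 250L,
                         adjust = FALSE) {
  stopifnot(is(deltaTrack, "CoverageTrack"))
  if (normState(deltaTrack) != "log2_ratio")
    stop("deltaByGroup expects a log2_ratio track")
  if (is.null(genes$quartile))
    genes <- assignExpressionQuartiles(genes)
  ln <- chromLengths(trackLayout(deltaTrack))
  w <- GRanges(genes$chrom,
               IRanges(pmax(1L, genes$tss - as.integer(windowHalfwidth)),
                       pmin(ln[genes$chrom],
                            genes$tss + as.integer(windowHalfwidth))))
  vals <- regionMeanSignal(deltaTrack, w)
  keep <- !is.na(vals)
  groups <- split(vals[keep], genes$quartile[keep])
  new("StratifiedResult", groups = groups,
      tests = .pairwiseMWU(groups, adjust = adjust),
      summary = .groupSummary(groups),
      excluded = sum(!keep))
}

#' Split peaks into top and bottom occupancy tertiles
#'
#' Scores each peak by its mean (or max) signal on an occupancy track, ranks
#' the peaks (ties broken by stable input order), and returns the top third
#' (`high`) and bottom third (`low`); the middle third is discarded. With
#' all-equal scores the split is size-balanced by stable order and a warning
#' is issued.
#'
#' @param peaks a `GRanges` of >= 3 peaks.
#' @param occupancyTrack a [CoverageTrack-class] (e.g. macroH2A1.1 coverage).
#' @param score `"mean"` (default, length-robust) or `"max"`.
#' @return list with `high` and `low` `GRanges` (each carrying a
#'   `tertile_score` metadata column) and the numeric `scores` of all peaks.
#' @export
stratifyBySignalTertiles <- function(peaks, occupancyTrack,
                                     score = c("mean", "max")) {
  score <- match.arg(score)
  n <- length(peaks)
  if (n < 3L) stop("need at least 3 peaks for tertiles")
  s <- regionMeanSignal(occupancyTrack, peaks)
  if (score == "max") {
    # max over bins touched by the peak
    bs <- binSize(occupancyTrack)
    chs <- as.character(seqnames(peaks))
    s <- vapply(seq_len(n), function(i) {
      v <- trackValues(occupancyTrack)[[chs[i]]]
      b1 <- (start(peaks)[i] - 1L) %/% bs + 1L
      b2 <- (end(peaks)[i] - 1L) %/% bs + 1L
      suppressWarnings(max(v[b1:min(b2, length(v))], na.rm = TRUE))
    }, numeric(1))
    s[!is.finite(s)] <- NA_real_
  }
  s2 <- ifelse(is.na(s), -Inf, s)
  if (length(unique(s2)) == 1L)
    warning("all peak scores equal; tertile split falls back to stable input order")
  ord <- order(s2, seq_len(n))  # stable tie-break
  k <- floor(n / 3)
  lowIdx <- sort(ord[seq_len(k)])
  highIdx <- sort(ord[(n - k + 1L):n])
  high <- peaks[highIdx]; low <- peaks[lowIdx]
  mcols(high)$tertile_score <- s[highIdx]
  mcols(low)$tertile_score <- s[lowIdx]
  list(high = high, low = low, scores = s)
}

#' Group values and pairwise tests of a StratifiedResult
#' @param x a [StratifiedResult-class].
#' @return `stratGroups`: named list of per-region values; `stratTests`:
#'   data.frame of pairwise Mann-Whitney results; `stratSummary`: per-group
#'   n/median/quartiles; `stratExcluded`: excluded region count.
#' @name strat-accessors
NULL

#' @rdname strat-accessors
#' @export
stratGroups <- function(x) { stopifnot(is(x, "StratifiedResult")); x@groups }
#' @rdname strat-accessors
#' @export
stratTests <- function(x) { stopifnot(is(x, "StratifiedResult")); x@tests }
#' @rdname strat-accessors
#' @export
stratSummary <- function(x) { stopifnot(is(x, "StratifiedResult")); x@summary }
#' @rdname strat-accessors
#' @export
stratExcluded <- function(x) { stopifnot(is(x, "StratifiedResult")); x@excluded }
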