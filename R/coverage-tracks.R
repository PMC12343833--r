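#' Bin fragment coverage into a genome-wide track
#'
#' Each bin's value is the number of fragment base pairs falling in the bin
#' divided by the bin width, i.e. mean per-base fragment depth. The last bin
#' of a chromosome may be short; its value still uses the nominal bin width
#' in the denominator so that total mass (sum of value x binSize) equals the
#' total fragment length exactly.
#'
#' @param frags a [FragmentSet-class] or a `GRanges` of fragments.
#' @param layout the governing [GenomeLayout-class].
#' @param binSize bin width in bp (>= 1).
#' @return a raw-state [CoverageTrack-class].
#' @examples
#' gl <- GenomeLayout("chr1", 1000L)
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' tr <- coverageFromFragments(fr, gl, binSize = 50L)
#' trackValues(tr)$chr1[1:3]
#' @export
coverageFromFragments <- function(frags, layout, binSize = 10L) {
  if (is(frags, "FragmentSet")) frags <- fragments(frags)
  stopifnot(is(layout, "GenomeLayout"))
  binSize <- as.integer(binSize)
  if (binSize < 1L) stop("binSize must be >= 1")
  ln <- chromLengths(layout)
  if (length(frags)) {
    bad <- !(as.character(seqnames(frags)) %in% names(ln))
    if (any(bad))
      stop("fragment on chromosome absent from layout: ",
           as.character(seqnames(frags))[bad][1L])
    if (any(start(frags) < 1L) ||
        any(end(frags) > ln[as.character(seqnames(frags))]))
      stop("fragment outside chromosome bounds")
  }
  frags <- GRanges(as.character(seqnames(frags)),
                   IRanges(start(frags), end(frags)),
                   seqinfo = layout@seqinfo)
  cov <- GenomicRanges::coverage(frags)
  values <- lapply(names(ln), function(ch) {
    L <- ln[[ch]]
    nb <- ceiling(L / binSize)
    starts <- (seq_len(nb) - 1L) * binSize + 1L
    ends <- pmin(starts + binSize - 1L, L)
    v <- IRanges::viewSums(IRanges::Views(cov[[ch]], start = starts, end = ends))
    as.numeric(v) / binSize
  })
  names(values) <- names(ln)
  new("CoverageTrack", layout = layout, binSize = binSize, values = values,
      normState = "raw")
}

#' Spike-in normalize a raw coverage track
#'
#' Multiplies every bin by `scaleConstant / spikeInCount`, the standard
#' scaled-per-spike-read normalization for exogenous spike-in libraries
#' (e.g. E. coli spike-in DNA in CUT&RUN). Only raw tracks may be scaled,
#' which enforces the pipeline order scale -> average -> ratio.
#'
#' @param track a raw [CoverageTrack-class].
#' @param spikeInCount spike-in fragment count of the library (> 0).
#' @param scaleConstant arbitrary constant (default 1e4); it cancels in every
#'   ratio and correlation statistic.
#' @return a `spike_scaled` [CoverageTrack-class].
#' @export
spikeInScale <- function(track, spikeInCount, scaleConstant = 1e4) {
  stopifnot(is(track, "CoverageTrack"))
  if (normState(track) != "raw")
    stop("spikeInScale requires a raw track (got '", normState(track),
         "'); scale before averaging or ratios")
  spikeInCount <- as.numeric(spikeInCount)
  if (length(spikeInCount) != 1L || is.na(spikeInCount) || spikeInCount <= 0)
    stop("spike-in normalization undefined for spikeInCount <= 0")
  f <- scaleConstant / spikeInCount
  values <- lapply(trackValues(track), function(v) v * f)
  new("CoverageTrack", layout = trackLayout(track), binSize = binSize(track),
      values = values, normState = "spike_scaled")
}

#' Z-normalize a coverage track
#'
#' Standardizes all defined bins to mean 0 and population SD 1:
#' Z = (score - mean) / SD, computed over every non-missing bin of the
#' genome. Masked bins stay masked.
#'
#' @param track a [CoverageTrack-class] with non-constant defined values.
#' @return a `znormalized` [CoverageTrack-class].
#' @export
znormalizeTrack <- function(track) {
  stopifnot(is(track, "CoverageTrack"))
  all_v <- unlist(trackValues(track), use.names = FALSE)
  def <- all_v[!is.na(all_v)]
  if (!length(def)) stop("track has no defined bins")
  mu <- mean(def)
  sdv <- sqrt(mean((def - mu)^2))  # population SD
  if (sdv == 0) stop("constant track: Z-normalization undefined (SD = 0)")
  values <- lapply(trackValues(track), function(v) (v - mu) / sdv)
  new("CoverageTrack", layout = trackLayout(track), binSize = binSize(track),
      values = values, normState = "znormalized")
}

#' Combine biological replicates
#'
#' Tracks are combined by per-bin arithmetic mean (the bigwig-averaging
#' convention); fragment sets are merged by concatenation with spike-in
#' counts summed (the read-depth-pooling convention used for CAD-Seq).
#'
#' @param inputs a list of >= 2 [CoverageTrack-class] objects (mode
#'   `"average_tracks"`) or >= 2 [FragmentSet-class] objects (mode
#'   `"merge_fragments"`).
#' @param mode `"average_tracks"` or `"merge_fragments"`.
#' @return a [CoverageTrack-class] or [FragmentSet-class].
#' @export
combineReplicates <- function(inputs,
                              mode = c("average_tracks", "merge_fragments")) {
  mode <- match.arg(mode)
  if (length(inputs) < 2L) stop("need at least 2 replicates to combine")
  if (mode == "average_tracks") {
    if (!all(vapply(inputs, is, logical(1), "CoverageTrack")))
      stop("average_tracks mode requires CoverageTrack inputs")
    ref <- inputs[[1L]]
    for (tr in inputs[-1L]) {
      if (!identical(chromLengths(trackLayout(tr)),
                     chromLengths(trackLayout(ref))) ||
          binSize(tr) != binSize(ref))
        stop("replicate tracks must share layout and bin size")
      if (normState(tr) != normState(ref))
        stop("replicate tracks must share normalization state")
    }
    values <- lapply(names(trackValues(ref)), function(ch) {
      m <- vapply(inputs, function(tr) trackValues(tr)[[ch]],
                  numeric(length(trackValues(ref)[[ch]])))
      rowMeans(m)
    })
    names(values) <- names(trackValues(ref))
    new("CoverageTrack", layout = trackLayout(ref), binSize = binSize(ref),
        values = values, normState = normState(ref))
  } else {
    if (!all(vapply(inputs, is, logical(1), "FragmentSet")))
      stop("merge_fragments mode requires FragmentSet inputs")
    fr <- do.call(c, lapply(inputs, fragments))
    FragmentSet(fr,
                spikeInCount = sum(vapply(inputs, spikeInCount, integer(1))),
                libraryLabel = paste(vapply(inputs, libraryLabel, character(1)),
                                     collapse = "+"))
  }
}

#' Log2 ratio of two coverage tracks
#'
#' Per-bin `log2((num + pseudocount) / (den + pseudocount))`. Bins where both
#' inputs are exactly 0 are masked (`NA`) rather than set to 0: absence of
#' signal in both conditions is no evidence of unchanged turnover. Inputs
#' must share layout, bin size and normalization state, and must not be
#' Z-normalized (negative values have no log ratio) or already ratios.
#'
#' @param numerator,denominator [CoverageTrack-class] objects in the same
#'   `raw` or `spike_scaled` state.
#' @param pseudocount positive stabilizer added to both (default 0.5).
#' @return a `log2_ratio` [CoverageTrack-class] with masked bins as `NA`.
#' @export
log2RatioTrack <- function(numerator, denominator, pseudocount = 0.5) {
  stopifnot(is(numerator, "CoverageTrack"), is(denominator, "CoverageTrack"))
  if (!identical(chromLengths(trackLayout(numerator)),
                 chromLengths(trackLayout(denominator))) ||
      binSize(numerator) != binSize(denominator))
    stop("ratio requires identical layout and bin size")
  if (normState(numerator) != normState(denominator))
    stop("normalization state mismatch: '", normState(numerator), "' vs '",
         normState(denominator), "'")
  if (!normState(numerator) %in% c("raw", "spike_scaled"))
    stop("log2 ratio is defined for raw or spike_scaled tracks, not '",
         normState(numerator), "'")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  values <- mapply(function(a, b) {
    r <- log2((a + pseudocount) / (b + pseudocount))
    r[!is.na(a) & !is.na(b) & a == 0 & b == 0] <- NA_real_
    r[is.na(a) | is.na(b)] <- NA_real_
    r
  }, trackValues(numerator), trackValues(denominator), SIMPLIFY = FALSE)
  new("CoverageTrack", layout = trackLayout(numerator),
      binSize = binSize(numerator), values = values, normState = "log2_ratio")
}

#' Pairwise correlation of coverage tracks
#'
#' Re-bins each track into equally sized windows (default 10 kb) — or
#' averages it over a supplied region set — and returns the matrix of
#' pairwise correlation coefficients. Windows where any track is undefined
#' are dropped (complete cases).
#'
#' @param tracks list of >= 2 [CoverageTrack-class] objects on one layout.
#' @param regions optional `GRanges`; when given, one averaged score per
#'   region replaces the genome-wide windows.
#' @param windowSize correlation window in bp (default 10000).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return symmetric matrix of coefficients with unit diagonal, labelled by
#'   track index or by `names(tracks)`.
#' @export
binnedCorrelation <- function(tracks, regions = NULL, windowSize = 10000L,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(tracks) < 2L) stop("need at least 2 tracks")
  ref <- tracks[[1L]]
  ln <- chromLengths(trackLayout(ref))
  for (tr in tracks[-1L])
    if (!identical(chromLengths(trackLayout(tr)), ln))
      stop("tracks must share one layout")
  if (is.null(regions)) {
    regions <- do.call(c, lapply(names(ln), function(ch) {
      starts <- seq(1L, ln[[ch]], by = as.integer(windowSize))
      GRanges(ch, IRanges(starts, pmin(starts + windowSize - 1L, ln[[ch]])))
    }))
  }
  scores <- vapply(tracks, function(tr) regionMeanSignal(tr, regions),
                   numeric(length(regions)))
  keep <- stats::complete.cases(scores)
  if (sum(keep) < 2L) stop("fewer than 2 usable windows for correlation")
  m <- stats::cor(scores[keep, , drop = FALSE], method = method)
  lbl <- if (!is.null(names(tracks))) names(tracks) else
    paste0("track", seq_along(tracks))
  dimnames(m) <- list(lbl, lbl)
  m
}
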