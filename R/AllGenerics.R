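#' Accessors for package classes
#'
#' Small accessor generics: chromosome names/lengths and blacklist of a
#' [GenomeLayout-class]; fragments and spike-in count of a
#' [FragmentSet-class]; bin size, values and normalization state of a
#' [CoverageTrack-class].
#'
#' @param x an object of the documented class.
#' @return the slot value (see Details of each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setGeneric("blacklist", function(x) standardGeneric("blacklist"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("spikeInCount", function(x) standardGeneric("spikeInCount"))
#' @rdname accessors
#' @export
setGeneric("libraryLabel", function(x) standardGeneric("libraryLabel"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("normState", function(x) standardGeneric("normState"))
#' @rdname accessors
#' @export
setGeneric("trackLayout", function(x) standardGeneric("trackLayout"))

#' Remove records overlapping the blacklist
#'
#' Every record (interval or fragment) overlapping any blacklist interval of
#' the layout by at least 1 bp is removed; all other records are kept in
#' their input order. The spike-in count of a [FragmentSet-class] is
#' unchanged (spike-in fragments live on the exogenous genome). An empty
#' blacklist makes this the identity, and the operation is idempotent.
#'
#' @param x a `GRanges` or a [FragmentSet-class].
#' @param layout the governing [GenomeLayout-class] carrying the blacklist.
#' @return an object of the same class as `x`.
#' @examples
#' gl <- GenomeLayout("chr1", 1000L,
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(551, 560)))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 501), c(100, 600)))
#' applyBlacklist(gr, gl)
#' @export
setGeneric("applyBlacklist", function(x, layout) standardGeneric("applyBlacklist"))

setMethod("chromNames", "GenomeLayout", function(x)
  GenomeInfoDb::seqnames(x@seqinfo))
setMethod("chromLengths", "GenomeLayout", function(x)
  GenomeInfoDb::seqlengths(x@seqinfo))
setMethod("blacklist", "GenomeLayout", function(x) x@blacklist)

setMethod("fragments", "FragmentSet", function(x) x@fragments)
setMethod("spikeInCount", "FragmentSet", function(x) x@spikeInCount)
setMethod("libraryLabel", "FragmentSet", function(x) x@libraryLabel)

setMethod("binSize", "CoverageTrack", function(x) x@binSize)
setMethod("trackValues", "CoverageTrack", function(x) x@values)
setMethod("normState", "CoverageTrack", function(x) x@normState)
setMethod("trackLayout", "CoverageTrack", function(x) x@layout)

setMethod("show", "GenomeLayout", function(object) {
  ln <- chromLengths(object)
  cat(sprintf("GenomeLayout: %d chromosome(s), %s bp total, %d blacklist interval(s)\n",
              length(ln), format(sum(as.numeric(ln)), big.mark = ","),
              length(object@blacklist)))
})

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet '%s': %d fragments, spike-in count %d\n",
              object@libraryLabel, length(object@fragments),
              object@spikeInCount))
})

setMethod("show", "CoverageTrack", function(object) {
  nb <- sum(lengths(object@values))
  nm <- sum(vapply(object@values, function(v) sum(is.na(v)), numeric(1)))
  cat(sprintf("CoverageTrack [%s]: bin %d bp, %d bins (%d masked)\n",
              object@normState, object@binSize, nb, as.integer(nm)))
})

setMethod("show", "SignalMatrix", function(object) {
  cat(sprintf("SignalMatrix '%s': %d anchors x %d bins (-%d/+%d bp @ %d bp)\n",
              object@trackLabel, nrow(object@values), ncol(object@values),
              object@upstream, object@downstream, object@binWidth))
})

setMethod("show", "StratifiedResult", function(object) {
  cat(sprintf("StratifiedResult: %d groups, %d pairwise tests, %d excluded\n",
              length(object@groups), nrow(object@tests), object@excluded))
  print(object@summary, row.names = FALSE)
})

setMethod("show", "JaccardResult", function(object) {
  cat(sprintf(
    "JaccardResult: observed %.4f | null mean %.4f (n = %d) | empirical p %.4g | z %.2f\n",
    object@observed, mean(object@nullValues), object@nShuffles,
    object@empiricalP, object@zScore))
})

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(
    "SimScenario: %d chrom (%s bp), %d genes, %d hotspots (%.0f%% TSS-linked), %d domains\n",
    length(object@chromLengths),
    format(sum(as.numeric(object@chromLengths)), big.mark = ","),
    object@nGenes, object@nHotspots, 100 * object@tssLinkedFraction,
    object@nDomains))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d genes, %d hotspots, %d domains (seed %d)\n",
              nrow(object@genes), length(object@hotspots),
              length(object@domains), object@seed))
})
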