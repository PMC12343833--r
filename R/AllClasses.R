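#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importClassesFrom GenomeInfoDb Seqinfo
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("integerOrNull", c("integer", "NULL"))

#' GenomeLayout: the coordinate universe
#'
#' A `GenomeLayout` holds the ordered chromosome names and lengths of a
#' (possibly synthetic) genome assembly together with a blacklist of regions
#' whose signal is considered artifactual and is excluded from all analyses.
#' Every interval, fragment and coverage track in the package is validated
#' against one layout.
#'
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] with unique names and positive lengths.
#' @slot blacklist a [GenomicRanges::GRanges] of excluded regions, each within
#'   its chromosome bounds (may be empty).
#'
#' @seealso [GenomeLayout()], [readChromSizes()], [applyBlacklist()]
#' @exportClass GenomeLayout
setClass("GenomeLayout",
  representation(seqinfo = "Seqinfo", blacklist = "GRanges"))

setValidity("GenomeLayout", function(object) {
  si <- object@seqinfo
  nm <- GenomeInfoDb::seqnames(si)
  ln <- GenomeInfoDb::seqlengths(si)
  if (anyDuplicated(nm)) return("duplicate chromosome names")
  if (length(ln) && (any(is.na(ln)) || any(ln <= 0)))
    return("chromosome lengths must be positive")
  bl <- object@blacklist
  if (length(bl)) {
    if (!all(as.character(seqnames(bl)) %in% nm))
      return("blacklist interval on unknown chromosome")
    if (any(start(bl) < 1) ||
        any(end(bl) > ln[as.character(seqnames(bl))]))
      return("blacklist interval outside chromosome bounds")
  }
  TRUE
})

#' Construct a GenomeLayout
#'
#' @param chromNames character vector of chromosome names (unique).
#' @param chromLengths integer vector of chromosome lengths in bp (> 0).
#' @param blacklist optional `GRanges` of blacklisted regions.
#' @return a [GenomeLayout-class] object.
#' @examples
#' gl <- GenomeLayout(c("chr1", "chr2"), c(1000L, 500L))
#' chromLengths(gl)
#' @export
GenomeLayout <- function(chromNames, chromLengths, blacklist = NULL) {
  si <- GenomeInfoDb::Seqinfo(seqnames = as.character(chromNames),
                              seqlengths = as.integer(chromLengths))
  if (is.null(blacklist)) {
    blacklist <- GRanges(seqinfo = si)
  } else {
    blacklist <- GRanges(seqnames = as.character(seqnames(blacklist)),
                         ranges = IRanges(start(blacklist), end(blacklist)),
                         seqinfo = si)
  }
  new("GenomeLayout", seqinfo = si, blacklist = blacklist)
}

#' FragmentSet: one aligned fragment library
#'
#' Simulated (or imported) aligned fragments for a single sequencing library,
#' downstream of alignment and deduplication. The count of fragments aligning
#' to the exogenous spike-in genome travels with the library so that coverage
#' can later be spike-in normalized.
#'
#' @slot fragments unstranded `GRanges` of fragment intervals.
#' @slot spikeInCount non-negative integer; fragments aligned to the spike-in
#'   genome (e.g. E. coli for CUT&RUN).
#' @slot libraryLabel character scalar naming the library.
#' @exportClass FragmentSet
setClass("FragmentSet",
  representation(fragments = "GRanges", spikeInCount = "integer",
                 libraryLabel = "character"))

setValidity("FragmentSet", function(object) {
  if (length(object@spikeInCount) != 1L || is.na(object@spikeInCount) ||
      object@spikeInCount < 0L)
    return("spikeInCount must be a single non-negative integer")
  if (length(object@libraryLabel) != 1L)
    return("libraryLabel must be a single string")
  TRUE
})

#' Construct a FragmentSet
#'
#' @param fragments `GRanges` of fragment intervals.
#' @param spikeInCount non-negative integer spike-in fragment count.
#' @param libraryLabel library name.
#' @return a [FragmentSet-class].
#' @export
FragmentSet <- function(fragments, spikeInCount = 0L, libraryLabel = "library") {
  new("FragmentSet", fragments = fragments,
      spikeInCount = as.integer(spikeInCount),
      libraryLabel = as.character(libraryLabel))
}

.TRACK_STATES <- c("raw", "spike_scaled", "znormalized", "log2_ratio")

#' CoverageTrack: binned genome-wide signal
#'
#' Fixed-bin-width numeric signal over a genome — the in-memory analog of a
#' bedGraph/bigWig file. Values are mean per-base depth (for raw tracks) or
#' whatever the recorded normalization state implies. Missing data (e.g. bins
#' masked in a log2-ratio track) are `NA`.
#'
#' @slot layout the governing [GenomeLayout-class].
#' @slot binSize positive integer bin width in bp.
#' @slot values named list, one numeric vector per chromosome of length
#'   `ceiling(length / binSize)`; `NA` marks missing bins.
#' @slot normState one of `"raw"`, `"spike_scaled"`, `"znormalized"`,
#'   `"log2_ratio"` — used to enforce the pipeline order (scale before
#'   average before ratio).
#' @seealso [coverageFromFragments()], [spikeInScale()], [znormalizeTrack()],
#'   [log2RatioTrack()]
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(layout = "GenomeLayout", binSize = "integer",
                 values = "list", normState = "character"))

setValidity("CoverageTrack", function(object) {
  if (object@binSize < 1L) return("binSize must be >= 1")
  if (!object@normState %in% .TRACK_STATES)
    return(sprintf("normState must be one of %s",
                   paste(.TRACK_STATES, collapse = ", ")))
  ln <- chromLengths(object@layout)
  if (!identical(names(object@values), names(ln)))
    return("values must have one vector per chromosome, in layout order")
  nb <- ceiling(ln / object@binSize)
  if (!all(lengths(object@values) == nb))
    return("per-chromosome value length must equal ceiling(length / binSize)")
  bad <- vapply(object@values,
                function(v) any(!is.finite(v) & !is.na(v)), logical(1))
  if (any(bad)) return("values must be finite where defined")
  TRUE
})

#' SignalMatrix: anchors x positional bins
#'
#' Strand-oriented matrix of track signal around reference points (TSSs, peak
#' midpoints). Rows follow the anchor order; columns span
#' `[-upstream, +downstream)` at `binWidth` resolution, with column 1 always
#' 5'-most relative to the anchor (minus-strand rows are orientation-flipped).
#' Cells whose window extends past a chromosome end are `NA`, not zero.
#'
#' @slot values numeric matrix (anchors x bins), `NA` = off-chromosome.
#' @slot upstream,downstream flank sizes in bp.
#' @slot binWidth positional bin width in bp.
#' @slot anchors data.frame with columns chrom, position, strand.
#' @slot trackLabel label of the source track.
#' @seealso [computeSignalMatrix()], [meanProfile()]
#' @exportClass SignalMatrix
setClass("SignalMatrix",
  representation(values = "matrix", upstream = "integer", downstream = "integer",
                 binWidth = "integer", anchors = "data.frame",
                 trackLabel = "character"))

setValidity("SignalMatrix", function(object) {
  nc <- (object@upstream + object@downstream) / object@binWidth
  if (ncol(object@values) != nc)
    return("column count must equal (upstream + downstream) / binWidth")
  if (nrow(object@values) != nrow(object@anchors))
    return("one row per anchor required")
  TRUE
})

#' StratifiedResult: grouped per-region statistics with pairwise tests
#'
#' Holds per-region statistic values partitioned into groups (expression
#' quartiles, occupancy tertiles), all pairwise two-sided Mann-Whitney U
#' tests between groups, per-group summaries, and the count of regions
#' excluded for having fully-missing signal.
#'
#' @slot groups named list of numeric vectors (one value per region).
#' @slot tests data.frame with columns groupA, groupB, U, p (and p_adj when
#'   Benjamini-Hochberg adjustment was requested).
#' @slot summary data.frame with columns group, n, median, q1, q3.
#' @slot excluded integer count of regions dropped (fully-missing windows).
#' @seealso [deltaByGroup()]
#' @exportClass StratifiedResult
setClass("StratifiedResult",
  representation(groups = "list", tests = "data.frame",
                 summary = "data.frame", excluded = "integer"))

setValidity("StratifiedResult", function(object) {
  if (nrow(object@tests) && (any(object@tests$p < 0) || any(object@tests$p > 1)))
    return("p values must lie in [0, 1]")
  TRUE
})

#' JaccardResult: observed vs permuted interval-set similarity
#'
#' Result of [permutationColocalization()]: the observed base-pair Jaccard
#' index of two interval sets, the permutation null distribution obtained by
#' randomly relocating the intervals within genome bounds, the add-one
#' empirical p value and a z-score against the null.
#'
#' @slot observed observed Jaccard index in [0, 1].
#' @slot nullValues numeric vector of permuted Jaccard indices.
#' @slot empiricalP add-one empirical p value, in (0, 1].
#' @slot zScore (observed - mean(null)) / sd(null).
#' @slot nShuffles number of permutations.
#' @slot seed RNG seed used (or NULL).
#' @exportClass JaccardResult
setClass("JaccardResult",
  representation(observed = "numeric", nullValues = "numeric",
                 empiricalP = "numeric", zScore = "numeric",
                 nShuffles = "integer", seed = "integerOrNull"))

setValidity("JaccardResult", function(object) {
  if (object@empiricalP <= 0 || object@empiricalP > 1)
    return("empiricalP must lie in (0, 1]")
  if (length(object@nullValues) &&
      (min(object@nullValues) < 0 || max(object@nullValues) > 1))
    return("null Jaccard values must lie in [0, 1]")
  TRUE
})

#' SimScenario: parameters of a synthetic study
#'
#' Bundles every parameter of the synthetic-data generator: genome geometry,
#' gene/expression model, TOP1 hotspot and macroH2A1.1 domain placement,
#' library parameters for CUT&RUN and CAD-Seq simulation, and the
#' condition/genotype parameters of the turnover model. Defaults define the
#' study conditions used throughout the test suite; see the methods vignette.
#'
#' @slot chromLengths named integer vector of chromosome lengths.
#' @slot nGenes number of genes (TSSs) to place.
#' @slot exprMeanlog,exprSdlog log-normal expression parameters.
#' @slot nHotspots number of TOP1 hotspots.
#' @slot hotspotWidthMean,hotspotWidthSd hotspot width distribution (bp).
#' @slot tssLinkedFraction fraction of hotspots centered on a sampled TSS.
#' @slot nDomains number of macroH2A1.1 domains.
#' @slot domainWidthMean,domainWidthSd domain width distribution (bp).
#' @slot hotspotCoverFraction fraction of hotspots targeted for domain coverage.
#' @slot blacklistFraction fraction of the genome covered by blacklist.
#' @slot blacklistWidth width of individual blacklist intervals (bp).
#' @slot cutrunFragments fragments per CUT&RUN library.
#' @slot cutrunFragLenMean,cutrunFragLenSd CUT&RUN fragment length (bp).
#' @slot enrichmentFold CUT&RUN enrichment of target over background.
#' @slot spikeFraction expected spike-in fraction of a library.
#' @slot cadRatePerBp steady-state CAD-Seq fragment rate per hotspot bp
#'   (lambda_s).
#' @slot cadBackgroundRate CAD-Seq background fragment rate per genome bp.
#' @slot cadFragLenMean,cadFragLenSd CAD-Seq fragment length (bp).
#' @slot deltaControl,deltaKd turnover-deficit parameter per genotype.
#' @slot rho protection strength of macroH2A1.1 occupancy in control cells.
#' @slot trackBinSize bin width of profile-grade coverage tracks (bp).
#' @slot rngSeed seed for genome construction.
#' @seealso [simScenario()], [buildSyntheticGenome()]
#' @exportClass SimScenario
setClass("SimScenario",
  representation(chromLengths = "integer", nGenes = "integer",
    exprMeanlog = "numeric", exprSdlog = "numeric",
    nHotspots = "integer", hotspotWidthMean = "numeric",
    hotspotWidthSd = "numeric", tssLinkedFraction = "numeric",
    nDomains = "integer", domainWidthMean = "numeric",
    domainWidthSd = "numeric", hotspotCoverFraction = "numeric",
    blacklistFraction = "numeric", blacklistWidth = "integer",
    cutrunFragments = "integer", cutrunFragLenMean = "numeric",
    cutrunFragLenSd = "numeric", enrichmentFold = "numeric",
    spikeFraction = "numeric",
    cadRatePerBp = "numeric", cadBackgroundRate = "numeric",
    cadFragLenMean = "numeric", cadFragLenSd = "numeric",
    deltaControl = "numeric", deltaKd = "numeric", rho = "numeric",
    trackBinSize = "integer", rngSeed = "integer"))

setValidity("SimScenario", function(object) {
  fr <- c(object@tssLinkedFraction, object@hotspotCoverFraction,
          object@blacklistFraction, object@spikeFraction)
  if (any(fr < 0 | fr > 1)) return("all fractions must lie in [0, 1]")
  if (object@cadRatePerBp <= 0) return("cadRatePerBp (lambda_s) must be > 0")
  if (object@deltaControl < 0 || object@deltaKd < 0)
    return("turnover-deficit delta must be >= 0")
  if (object@hotspotWidthMean <= 0 || object@domainWidthMean <= 0)
    return("feature widths must be positive")
  if (any(object@chromLengths <= 0)) return("chromosome lengths must be > 0")
  TRUE
})

#' SimTruth: ground truth of a synthetic genome
#'
#' Everything needed to recompute expected values in recovery tests: the true
#' TOP1 hotspots (with normalized expression `e`, binary occupancy `m`, and
#' TSS linkage), the true macroH2A1.1 domains, the gene table, the scenario
#' and the seed.
#'
#' @slot layout the [GenomeLayout-class] of the synthetic genome.
#' @slot genes gene table data.frame (gene_id, chrom, tss, strand, expression).
#' @slot hotspots `GRanges` with mcols `hotspot_id`, `gene_id`, `e`, `m`,
#'   `is_tss`.
#' @slot domains `GRanges` of macroH2A1.1 domains.
#' @slot scenario the generating [SimScenario-class].
#' @slot seed the seed used.
#' @exportClass SimTruth
setClass("SimTruth",
  representation(layout = "GenomeLayout", genes = "data.frame",
                 hotspots = "GRanges", domains = "GRanges",
                 scenario = "SimScenario", seed = "integer"))
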