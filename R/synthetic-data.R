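#' Construct a simulation scenario
#'
#' Defaults define the study conditions used throughout the package: a
#' 4 x 2 Mbp genome with 400 genes, 300 TOP1 hotspots (70% TSS-linked) and
#' 180 macroH2A1.1 domains placed to cover half of the hotspots; log-normal
#' gene expression; CUT&RUN libraries with 20-fold target enrichment and a
#' 1% spike-in fraction; CAD-Seq libraries with a steady-state hotspot rate
#' of 0.2 fragments per bp; and a turnover model in which prolonged damage
#' amplifies hotspot signal by `1 + delta * e * (1 - rho * m)` in control
#' cells (`m` = macroH2A1.1 occupancy, `e` = normalized expression of the
#' linked gene) and by `1 + delta * e` after macroH2A1.1 knockdown. See the
#' methods vignette for the rationale of each default.
#'
#' @param chromLengths named integer vector of chromosome lengths (bp).
#' @param nGenes,exprMeanlog,exprSdlog gene count and log-normal expression
#'   parameters.
#' @param nHotspots,hotspotWidthMean,hotspotWidthSd,tssLinkedFraction TOP1
#'   hotspot parameters.
#' @param nDomains,domainWidthMean,domainWidthSd,hotspotCoverFraction
#'   macroH2A1.1 domain parameters.
#' @param blacklistFraction,blacklistWidth blacklist geometry.
#' @param cutrunFragments,cutrunFragLenMean,cutrunFragLenSd,enrichmentFold,spikeFraction
#'   CUT&RUN library parameters.
#' @param cadRatePerBp,cadBackgroundRate,cadFragLenMean,cadFragLenSd CAD-Seq
#'   library parameters (`cadRatePerBp` is the steady-state intensity
#'   lambda_s per hotspot bp).
#' @param deltaControl,deltaKd,rho turnover-deficit and protection
#'   parameters per genotype.
#' @param trackBinSize profile-grade track bin width (bp).
#' @param rngSeed seed used by [buildSyntheticGenome()].
#' @return a [SimScenario-class].
#' @export
simScenario <- function(chromLengths = c(chr1 = 2e6, chr2 = 2e6,
                                         chr3 = 2e6, chr4 = 2e6),
                        nGenes = 400L, exprMeanlog = 1, exprSdlog = 1,
                        nHotspots = 300L, hotspotWidthMean = 1000,
                        hotspotWidthSd = 200, tssLinkedFraction = 0.7,
                        nDomains = 180L, domainWidthMean = 5000,
                        domainWidthSd = 1000, hotspotCoverFraction = 0.5,
                        blacklistFraction = 0.005, blacklistWidth = 2000L,
                        cutrunFragments = 100000L, cutrunFragLenMean = 150,
                        cutrunFragLenSd = 25, enrichmentFold = 20,
                        spikeFraction = 0.01,
                        cadRatePerBp = 0.2, cadBackgroundRate = 0.001,
                        cadFragLenMean = 1000, cadFragLenSd = 200,
                        deltaControl = 1, deltaKd = 1, rho = 1,
                        trackBinSize = 10L, rngSeed = 1L) {
  new("SimScenario",
      chromLengths = stats::setNames(as.integer(chromLengths),
                                     names(chromLengths)),
      nGenes = as.integer(nGenes), exprMeanlog = exprMeanlog,
      exprSdlog = exprSdlog, nHotspots = as.integer(nHotspots),
      hotspotWidthMean = hotspotWidthMean, hotspotWidthSd = hotspotWidthSd,
      tssLinkedFraction = tssLinkedFraction, nDomains = as.integer(nDomains),
      domainWidthMean = domainWidthMean, domainWidthSd = domainWidthSd,
      hotspotCoverFraction = hotspotCoverFraction,
      blacklistFraction = blacklistFraction,
      blacklistWidth = as.integer(blacklistWidth),
      cutrunFragments = as.integer(cutrunFragments),
      cutrunFragLenMean = cutrunFragLenMean,
      cutrunFragLenSd = cutrunFragLenSd, enrichmentFold = enrichmentFold,
      spikeFraction = spikeFraction, cadRatePerBp = cadRatePerBp,
      cadBackgroundRate = cadBackgroundRate, cadFragLenMean = cadFragLenMean,
      cadFragLenSd = cadFragLenSd, deltaControl = deltaControl,
      deltaKd = deltaKd, rho = rho, trackBinSize = as.integer(trackBinSize),
      rngSeed = as.integer(rngSeed))
}

# uniform random positions avoiding a set of forbidden linear intervals
.placeAvoiding <- function(n, lengths, offsets, forbidden, margin = 0,
                           maxRounds = 200L) {
  if (!n) return(list(ci = integer(0), pos = numeric(0)))
  L <- as.numeric(lengths)
  usable <- pmax(0, L - 2 * margin)
  if (sum(usable) <= 0) stop("infeasible placement: no usable genome space")
  ci <- integer(n); pos <- numeric(n)
  todo <- seq_len(n)
  for (round in seq_len(maxRounds)) {
    m <- length(todo)
    u <- stats::runif(m) * sum(usable)
    cum <- cumsum(usable)
    c2 <- findInterval(u, cum) + 1L
    p <- margin + (u - c(0, cum)[c2])
    ci[todo] <- c2; pos[todo] <- floor(p)
    lin <- offsets[c2] + pos[todo]
    bad <- .membership(lin, forbidden)
    todo <- todo[bad]
    if (!length(todo)) break
  }
  if (length(todo)) stop("infeasible placement after ", maxRounds, " rounds")
  list(ci = ci, pos = pos)  # pos is 0-based within chromosome
}

#' Build a synthetic genome with ground truth
#'
#' Lays out chromosomes and a blacklist, places TSSs (avoiding the
#' blacklist) with i.i.d. log-normal expression, places TOP1 hotspots — a
#' `tssLinkedFraction` of them centered on TSSs sampled with probability
#' proportional to expression, the remainder uniform at random and at least
#' 10 kb from any TSS — and macroH2A1.1 domains covering a
#' `hotspotCoverFraction` of hotspot midpoints (the rest placed uniformly).
#' Hotspots are mutually disjoint. The returned truth records, per hotspot,
#' the normalized expression `e` (empirical CDF rank of the linked gene; 0
#' for non-TSS hotspots) and the binary occupancy `m` (any domain covers the
#' hotspot midpoint), recomputed from the final domain placement.
#'
#' @param scenario a [SimScenario-class].
#' @param seed optional seed overriding `scenario@rngSeed`.
#' @return a [SimTruth-class].
#' @export
buildSyntheticGenome <- function(scenario, seed = NULL) {
  stopifnot(is(scenario, "SimScenario"))
  seed <- if (is.null(seed)) scenario@rngSeed else as.integer(seed)
  set.seed(seed)
  ln <- scenario@chromLengths
  if (is.null(names(ln))) names(ln) <- paste0("chr", seq_along(ln))
  off <- .chromOffsets(ln)
  G <- sum(as.numeric(ln))

  # blacklist
  nBl <- round(scenario@blacklistFraction * G / scenario@blacklistWidth)
  blGr <- GRanges()
  blFlat <- list(s = numeric(0), e = numeric(0))
  if (nBl > 0) {
    bw <- scenario@blacklistWidth
    pl <- .placeAvoiding(nBl, ln - bw, off, list(s = numeric(0), e = numeric(0)),
                         margin = 0)
    blGr <- GRanges(names(ln)[pl$ci], IRanges(pl$pos + 1L, width = bw))
    blFlat <- .flatten0(off[pl$ci] + pl$pos, off[pl$ci] + pl$pos + bw)
  }
  layout <- GenomeLayout(names(ln), ln, blacklist = blGr)

  # genes: TSS placement avoiding blacklist, 5 kb margin from chromosome ends
  nG <- scenario@nGenes
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      tss = integer(0), strand = character(0),
                      expression = numeric(0))
  if (nG > 0) {
    pl <- .placeAvoiding(nG, ln, off, blFlat, margin = 5000)
    expression <- stats::rlnorm(nG, meanlog = scenario@exprMeanlog,
                                sdlog = scenario@exprSdlog)
    genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(nG)),
                        chrom = names(ln)[pl$ci],
                        tss = as.integer(pl$pos + 1L),
                        strand = sample(c("+", "-"), nG, replace = TRUE),
                        expression = expression)
  }

  # hotspots: TSS-linked (expression-weighted, without replacement) + distal
  nH <- scenario@nHotspots
  hs <- GRanges(seqinfo = layout@seqinfo)
  if (nH > 0) {
    widths <- pmax(200, round(stats::rnorm(nH, scenario@hotspotWidthMean,
                                           scenario@hotspotWidthSd)))
    nLinked <- round(scenario@tssLinkedFraction * nH)
    nLinked <- min(nLinked, nG)
    linkedGenes <- if (nLinked > 0)
      sample(seq_len(nG), nLinked, prob = genes$expression) else integer(0)
    chrom <- character(nH); center <- numeric(nH)
    geneOf <- rep(NA_character_, nH)
    isTss <- c(rep(TRUE, nLinked), rep(FALSE, nH - nLinked))
    if (nLinked > 0) {
      chrom[seq_len(nLinked)] <- genes$chrom[linkedGenes]
      center[seq_len(nLinked)] <- genes$tss[linkedGenes]
      geneOf[seq_len(nLinked)] <- genes$gene_id[linkedGenes]
    }
    # distal hotspots: uniform, >10 kb from every TSS, clear of blacklist
    nDist <- nH - nLinked
    if (nDist > 0) {
      tssForbid <- .flatten0(off[match(genes$chrom, names(ln))] + genes$tss -
                               1 - 10000,
                             off[match(genes$chrom, names(ln))] + genes$tss +
                               10000)
      forbid <- .flatten0(c(blFlat$s, tssForbid$s), c(blFlat$e, tssForbid$e))
      pl <- .placeAvoiding(nDist, ln, off, forbid, margin = 5000)
      chrom[(nLinked + 1L):nH] <- names(ln)[pl$ci]
      center[(nLinked + 1L):nH] <- pl$pos + 1
    }
    starts <- pmax(1, round(center - widths / 2))
    ends <- pmin(ln[chrom], starts + widths - 1)
    hs <- GRanges(chrom, IRanges(starts, ends), seqinfo = layout@seqinfo)
    # enforce disjoint hotspots: drop later-placed overlappers, then re-place
    repeat {
      ov <- GenomicRanges::findOverlaps(hs, drop.self = TRUE,
                                        drop.redundant = TRUE)
      if (!length(ov)) break
      drop <- unique(S4Vectors::subjectHits(ov))
      keep <- setdiff(seq_along(hs), drop)
      # relocate dropped distal-style, uniform and disjoint from the rest
      forbid2 <- do.call(.flatten0, .linearize(hs[keep], off))
      forbid2 <- .flatten0(c(forbid2$s, blFlat$s), c(forbid2$e, blFlat$e))
      pl <- .placeAvoiding(length(drop), ln, off, forbid2, margin = 5000)
      w2 <- width(hs)[drop]
      hs2s <- pmax(1, round(pl$pos + 1 - w2 / 2))
      hs2 <- GRanges(names(ln)[pl$ci],
                     IRanges(hs2s, pmin(ln[names(ln)[pl$ci]], hs2s + w2 - 1)),
                     seqinfo = layout@seqinfo)
      isTss[drop] <- FALSE; geneOf[drop] <- NA_character_
      hs <- c(hs[keep], hs2)
      perm <- c(keep, drop)
      isTss <- isTss[perm]; geneOf <- geneOf[perm]
    }
    mcols(hs)$hotspot_id <- sprintf("hs%04d", seq_along(hs))
    mcols(hs)$gene_id <- geneOf
    mcols(hs)$is_tss <- isTss
    # normalized expression: empirical CDF rank in (0, 1]; 0 for distal
    eRank <- rank(genes$expression, ties.method = "first") / max(1L, nG)
    e <- rep(0, length(hs))
    hit <- match(geneOf, genes$gene_id)
    e[!is.na(hit)] <- eRank[hit[!is.na(hit)]]
    mcols(hs)$e <- e
  }

  # macroH2A1.1 domains: cover a fraction of hotspot midpoints, rest uniform
  nD <- scenario@nDomains
  dom <- GRanges(seqinfo = layout@seqinfo)
  if (nD > 0) {
    dw <- pmax(500, round(stats::rnorm(nD, scenario@domainWidthMean,
                                       scenario@domainWidthSd)))
    nCover <- min(round(scenario@hotspotCoverFraction * length(hs)), nD)
    chrom <- character(nD); center <- numeric(nD)
    if (nCover > 0) {
      covered <- sample(seq_along(hs), nCover)
      mid <- floor((start(hs)[covered] + end(hs)[covered]) / 2)
      jitter <- round(stats::runif(nCover, -0.3, 0.3) * dw[seq_len(nCover)])
      chrom[seq_len(nCover)] <- as.character(seqnames(hs))[covered]
      center[seq_len(nCover)] <- mid + jitter
    }
    if (nD > nCover) {
      pl <- .placeAvoiding(nD - nCover, ln, off, blFlat, margin = 5000)
      chrom[(nCover + 1L):nD] <- names(ln)[pl$ci]
      center[(nCover + 1L):nD] <- pl$pos + 1
    }
    starts <- pmax(1, round(center - dw / 2))
    ends <- pmin(ln[chrom], starts + dw - 1)
    dom <- GRanges(chrom, IRanges(starts, ends), seqinfo = layout@seqinfo)
  }

  # occupancy truth from final placement
  if (length(hs)) {
    mids <- midpointAnchors(hs)
    mcols(hs)$m <- as.integer(
      GenomicRanges::countOverlaps(mids, dom, ignore.strand = TRUE) > 0L)
  }
  new("SimTruth", layout = layout, genes = genes, hotspots = hs,
      domains = dom, scenario = scenario, seed = seed)
}

#' Truth accessors
#' @param x a [SimTruth-class].
#' @return `truthLayout`: the [GenomeLayout-class]; `truthGenes`: gene table;
#'   `truthHotspots` / `truthDomains`: `GRanges`; `truthScenario`: the
#'   generating [SimScenario-class].
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
truthLayout <- function(x) { stopifnot(is(x, "SimTruth")); x@layout }
#' @rdname truth-accessors
#' @export
truthGenes <- function(x) { stopifnot(is(x, "SimTruth")); x@genes }
#' @rdname truth-accessors
#' @export
truthHotspots <- function(x) { stopifnot(is(x, "SimTruth")); x@hotspots }
#' @rdname truth-accessors
#' @export
truthDomains <- function(x) { stopifnot(is(x, "SimTruth")); x@domains }
#' @rdname truth-accessors
#' @export
truthScenario <- function(x) { stopifnot(is(x, "SimTruth")); x@scenario }

# uniform 0-based linear midpoints over the genome (chromosome-weighted)
.uniformMidpoints <- function(n, lengths, offsets) {
  if (!n) return(numeric(0))
  L <- as.numeric(lengths)
  ci <- sample.int(length(L), n, replace = TRUE, prob = L)
  offsets[ci] + floor(stats::runif(n) * L[ci])
}

.sampleFragments <- function(n, midLin, offsets, lenMean, lenSd,
                             minLen, maxLen, ln) {
  # midLin: 0-based linear midpoints; returns GRanges clipped to bounds
  if (!n) return(NULL)
  fl <- pmin(maxLen, pmax(minLen, round(stats::rnorm(n, lenMean, lenSd))))
  ci <- findInterval(midLin, offsets)
  posInChrom <- midLin - offsets[ci]  # 0-based
  s <- pmax(0, round(posInChrom - fl / 2))
  e <- pmin(as.numeric(ln[ci]), s + fl)
  s <- pmin(s, e - 1)
  GRanges(names(ln)[ci], IRanges(s + 1, e))
}

#' Simulate a CUT&RUN fragment library
#'
#' Fragment midpoints are drawn from a mixture of uniform genomic background
#' and, for the named target, placement within that target's true intervals,
#' weighted so that mean coverage over target intervals exceeds background
#' by the scenario's enrichment fold. IgG libraries are pure background. The
#' spike-in count is drawn binomially from the scenario spike fraction.
#'
#' @param truth a [SimTruth-class].
#' @param target `"TOP1"`, `"macroH2A1.1"` or `"IgG"`.
#' @param seed integer seed for this library.
#' @param nFragments optional override of the scenario fragment count.
#' @return a [FragmentSet-class].
#' @export
simulateCutrunFragments <- function(truth, target = c("TOP1", "macroH2A1.1",
                                                      "IgG"),
                                    seed = 1L, nFragments = NULL) {
  stopifnot(is(truth, "SimTruth"))
  target <- match.arg(target)
  sc <- truth@scenario
  set.seed(as.integer(seed))
  n <- if (is.null(nFragments)) sc@cutrunFragments else as.integer(nFragments)
  lbl <- paste0("cutrun_", target, "_seed", seed)
  if (n == 0L)
    return(FragmentSet(GRanges(seqinfo = truth@layout@seqinfo), 0L, lbl))
  spike <- stats::rbinom(1L, n, sc@spikeFraction)
  ng <- n - spike
  ln <- chromLengths(truth@layout)
  off <- .chromOffsets(ln)
  G <- sum(as.numeric(ln))
  tgt <- switch(target, TOP1 = truth@hotspots, macroH2A1.1 = truth@domains,
                IgG = GRanges())
  tgtFlat <- if (length(tgt)) do.call(.flatten0, .linearize(tgt, off)) else
    list(s = numeric(0), e = numeric(0))
  Tbp <- .coveredBp(tgtFlat)
  # mixture weight giving target/background mean-density ratio == fold:
  # background stays uniform over the whole genome, the target component
  # contributes the extra (fold - 1) weight
  if (sc@enrichmentFold < 1) stop("enrichmentFold must be >= 1")
  pTarget <- if (Tbp > 0 && target != "IgG")
    (sc@enrichmentFold - 1) * Tbp / ((sc@enrichmentFold - 1) * Tbp + G) else 0
  fromTarget <- stats::runif(ng) < pTarget
  midLin <- numeric(ng)
  nT <- sum(fromTarget)
  if (nT > 0) {
    # uniform over target bp: invert the flattened cumulative coverage
    cumW <- cumsum(tgtFlat$e - tgtFlat$s)
    u <- stats::runif(nT) * sum(tgtFlat$e - tgtFlat$s)
    iv <- findInterval(u, cumW) + 1L
    midLin[fromTarget] <- tgtFlat$s[iv] + (u - c(0, cumW)[iv])
  }
  if (ng - nT > 0) midLin[!fromTarget] <- .uniformMidpoints(ng - nT, ln, off)
  if (!ng)
    return(FragmentSet(GRanges(seqinfo = truth@layout@seqinfo), spike, lbl))
  fr <- .sampleFragments(ng, floor(midLin), off, sc@cutrunFragLenMean,
                         sc@cutrunFragLenSd, 50, 500, ln)
  fr <- GRanges(seqnames(fr), IRanges(start(fr), end(fr)),
                seqinfo = truth@layout@seqinfo)
  FragmentSet(fr, spikeInCount = spike, libraryLabel = lbl)
}

#' Simulate a CAD-Seq fragment library
#'
#' Per hotspot `h` with normalized expression `e_h` (0 for TSS-distal
#' hotspots) and binary macroH2A1.1 occupancy `m_h`, the steady-state
#' condition (brief CPT pulse) emits `Poisson(lambda_s * w_h)` fragments and
#' the prolonged-damage condition (30' CPT) emits
#' `Poisson(lambda_s * w_h * (1 + delta_g * e_h * (1 - rho * m_h * [g == control])))`
#' fragments, so that in control cells macroH2A1.1-covered hotspots
#' accumulate no damage-induced TOP1cc signal while knockdown cells
#' accumulate in proportion to transcription. Uniform background fragments
#' are added at the scenario rate; all draws are seeded.
#'
#' @param truth a [SimTruth-class].
#' @param condition `"steady_5min"` or `"prolonged_30min"`.
#' @param genotype `"control"` or `"macroH2A1_1_KD"`.
#' @param seed integer seed for this library.
#' @return a [FragmentSet-class].
#' @export
simulateCadseqFragments <- function(truth,
                                    condition = c("steady_5min",
                                                  "prolonged_30min"),
                                    genotype = c("control", "macroH2A1_1_KD"),
                                    seed = 1L) {
  stopifnot(is(truth, "SimTruth"))
  condition <- match.arg(condition)
  genotype <- match.arg(genotype)
  sc <- truth@scenario
  set.seed(as.integer(seed))
  ln <- chromLengths(truth@layout)
  off <- .chromOffsets(ln)
  G <- sum(as.numeric(ln))
  hs <- truth@hotspots
  lbl <- sprintf("cad_%s_%s_seed%d", condition, genotype, seed)
  delta <- if (genotype == "control") sc@deltaControl else sc@deltaKd
  factor <- rep(1, length(hs))
  if (condition == "prolonged_30min" && length(hs)) {
    e <- mcols(hs)$e
    m <- mcols(hs)$m
    protect <- if (genotype == "control") sc@rho * m else 0
    factor <- 1 + delta * e * (1 - protect)
  }
  midLin <- numeric(0)
  if (length(hs)) {
    lam <- sc@cadRatePerBp * as.numeric(width(hs)) * factor
    counts <- stats::rpois(length(hs), lam)
    if (sum(counts)) {
      hIdx <- rep(seq_along(hs), counts)
      u <- stats::runif(sum(counts))
      hLin <- .linearize(hs, off)
      midLin <- hLin$s[hIdx] + u * (hLin$e[hIdx] - hLin$s[hIdx])
    }
  }
  nBg <- stats::rpois(1L, sc@cadBackgroundRate * G)
  if (nBg > 0) midLin <- c(midLin, .uniformMidpoints(nBg, ln, off))
  nTot <- length(midLin)
  if (!nTot)
    return(FragmentSet(GRanges(seqinfo = truth@layout@seqinfo), 0L, lbl))
  fr <- .sampleFragments(nTot, floor(midLin), off, sc@cadFragLenMean,
                         sc@cadFragLenSd, 200, 2000, ln)
  fr <- GRanges(seqnames(fr), IRanges(start(fr), end(fr)),
                seqinfo = truth@layout@seqinfo)
  # spike-in reads come from a fixed amount of exogenous DNA, independent of
  # the genomic adduct load: Poisson around the steady-state expectation
  expectedSteady <- sc@cadRatePerBp * sum(as.numeric(width(hs))) +
    sc@cadBackgroundRate * G
  spike <- max(1L, stats::rpois(1L, sc@spikeFraction * expectedSteady))
  FragmentSet(fr, spikeInCount = spike, libraryLabel = lbl)
}
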