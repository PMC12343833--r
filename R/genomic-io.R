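#' Read a chrom.sizes file
#'
#' Parses the standard two-column (name, length) whitespace-delimited genome
#' layout file used by genome browsers and interval tools.
#'
#' @param path path to a chrom.sizes file.
#' @param blacklist optional `GRanges` (or path to a BED file) of blacklisted
#'   regions to attach to the layout.
#' @return a [GenomeLayout-class] with chromosomes in file order.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), f)
#' readChromSizes(f)
#' @export
readChromSizes <- function(path, blacklist = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty chrom.sizes file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nm <- character(length(fields)); ln <- integer(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2L)
      stop(sprintf("malformed chrom.sizes line %d: expected 2 columns", i))
    len <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(len) || len <= 0 || len != floor(len))
      stop(sprintf("chrom.sizes line %d: non-positive or non-integer length '%s'",
                   i, f[2L]))
    nm[i] <- f[1L]; ln[i] <- as.integer(len)
  }
  if (anyDuplicated(nm))
    stop(sprintf("chrom.sizes line %d: duplicate chromosome name '%s'",
                 which(duplicated(nm))[1L], nm[duplicated(nm)][1L]))
  layout <- GenomeLayout(nm, ln)
  if (!is.null(blacklist)) {
    if (is.character(blacklist)) blacklist <- parseBed(blacklist, layout)
    layout <- GenomeLayout(nm, ln, blacklist = blacklist)
  }
  layout
}

#' Parse a BED file against a genome layout
#'
#' Reads BED3/BED6 text (0-based half-open on disk) into a 1-based `GRanges`
#' validated against `layout`. Strand is taken from column 6 when present;
#' a numeric column 5 becomes the `score` metadata column. Columns beyond 6
#' are ignored.
#'
#' @param path path to a BED file.
#' @param layout a [GenomeLayout-class] defining valid chromosomes and bounds.
#' @param strict if `TRUE` (default) records on unknown chromosomes are an
#'   error; if `FALSE` they are skipped with a warning. Coordinate violations
#'   (start >= end, end beyond the chromosome) are always errors, reported
#'   with their line number.
#' @return a `GRanges` with `seqinfo` from `layout`.
#' @seealso [writeBed()]
#' @export
parseBed <- function(path, layout, strict = TRUE) {
  stopifnot(is(layout, "GenomeLayout"))
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  ln <- chromLengths(layout)
  if (!length(lines))
    return(GRanges(seqinfo = layout@seqinfo))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop(sprintf("BED line %d: fewer than 3 columns", lineno[which(ncols < 3L)[1L]]))
  chrom <- vapply(fields, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(start0) || anyNA(end0))
    stop(sprintf("BED line %d: non-numeric coordinates",
                 lineno[which(is.na(start0) | is.na(end0))[1L]]))
  known <- chrom %in% names(ln)
  if (!all(known)) {
    i <- which(!known)[1L]
    msg <- sprintf("BED line %d: unknown chromosome '%s'", lineno[i], chrom[i])
    if (strict) stop(msg)
    warning(msg, "; skipping ", sum(!known), " record(s)")
    fields <- fields[known]; chrom <- chrom[known]
    start0 <- start0[known]; end0 <- end0[known]
    lineno <- lineno[known]; ncols <- ncols[known]
  }
  if (!length(chrom)) return(GRanges(seqinfo = layout@seqinfo))
  if (any(start0 >= end0)) {
    i <- which(start0 >= end0)[1L]
    stop(sprintf("BED line %d: start (%g) must be < end (%g)",
                 lineno[i], start0[i], end0[i]))
  }
  if (any(start0 < 0))
    stop(sprintf("BED line %d: negative start", lineno[which(start0 < 0)[1L]]))
  over <- end0 > ln[chrom]
  if (any(over)) {
    i <- which(over)[1L]
    stop(sprintf("BED line %d: end %g beyond chromosome '%s' length %d",
                 lineno[i], end0[i], chrom[i], ln[chrom[i]]))
  }
  strand <- rep("*", length(chrom))
  has6 <- ncols >= 6L
  if (any(has6)) {
    s6 <- vapply(fields[has6], `[`, character(1), 6L)
    s6[!s6 %in% c("+", "-")] <- "*"
    strand[has6] <- s6
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand,
                seqinfo = layout@seqinfo)
  has5 <- ncols >= 5L
  if (any(has5)) {
    sc <- rep(NA_real_, length(chrom))
    sc[has5] <- suppressWarnings(
      as.numeric(vapply(fields[has5], `[`, character(1), 5L)))
    if (!all(is.na(sc))) mcols(gr)$score <- sc
  }
  has4 <- ncols >= 4L
  if (any(has4)) {
    nm <- rep(NA_character_, length(chrom))
    nm[has4] <- vapply(fields[has4], `[`, character(1), 4L)
    mcols(gr)$name <- nm
  }
  gr
}

#' Write a GRanges to BED
#'
#' Emits tab-delimited, newline-terminated BED (0-based half-open). BED6 is
#' written when any record carries a strand or score; otherwise BED3 (plus a
#' name column when present).
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeBed <- function(gr, path) {
  chrom <- as.character(seqnames(gr))
  s0 <- start(gr) - 1L
  e0 <- end(gr)
  str <- as.character(strand(gr))
  hasStrand <- any(str != "*")
  score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else NULL
  name <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else NULL
  if (hasStrand || !is.null(score)) {
    nm <- if (is.null(name)) paste0("rec", seq_along(gr)) else name
    sc <- if (is.null(score)) rep(0, length(gr)) else ifelse(is.na(score), 0, score)
    df <- data.frame(chrom, s0, e0, nm, sc, str)
  } else if (!is.null(name)) {
    df <- data.frame(chrom, s0, e0, name)
  } else {
    df <- data.frame(chrom, s0, e0)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a CoverageTrack to bedGraph
#'
#' Writes the 4-column bedGraph representation (0-based half-open), sorted by
#' chromosome then start, with runs of equal-valued adjacent bins collapsed
#' into single lines and `NA` (masked) bins omitted.
#'
#' @param track a [CoverageTrack-class].
#' @param path output path.
#' @param digits significant digits for values (default 6).
#' @return invisibly, `path`.
#' @export
writeBedGraph <- function(track, path, digits = 6L) {
  ln <- chromLengths(trackLayout(track))
  bs <- binSize(track)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(ln)) {
    v <- signif(trackValues(track)[[ch]], digits)
    nb <- length(v)
    if (!nb) next
    starts0 <- (seq_len(nb) - 1L) * bs
    ends0 <- pmin(starts0 + bs, ln[[ch]])
    r <- rle(ifelse(is.na(v), "NA", format(v, scientific = FALSE, trim = TRUE)))
    idxEnd <- cumsum(r$lengths)
    idxStart <- idxEnd - r$lengths + 1L
    ok <- r$values != "NA"
    if (!any(ok)) next
    writeLines(paste(ch, starts0[idxStart[ok]], ends0[idxEnd[ok]],
                     r$values[ok], sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph into a CoverageTrack
#'
#' Inverse of [writeBedGraph()] for tracks whose intervals align to a fixed
#' bin grid. Bases not covered by any bedGraph line become `NA`.
#'
#' @param path bedGraph file path.
#' @param layout governing [GenomeLayout-class].
#' @param binSize bin width of the resulting track (bp).
#' @param normState normalization tag to record (default `"raw"`).
#' @return a [CoverageTrack-class].
#' @export
readBedGraph <- function(path, layout, binSize, normState = "raw") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  ln <- chromLengths(layout)
  unknown <- setdiff(unique(df$chrom), names(ln))
  if (length(unknown))
    stop("bedGraph references unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  binSize <- as.integer(binSize)
  values <- lapply(names(ln), function(ch) {
    nb <- ceiling(ln[[ch]] / binSize)
    v <- rep(NA_real_, nb)
    d <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(d)) {
      for (i in seq_len(nrow(d))) {
        b1 <- floor(d$start[i] / binSize) + 1L
        b2 <- ceiling(d$end[i] / binSize)
        v[b1:b2] <- d$value[i]
      }
    }
    v
  })
  names(values) <- names(ln)
  new("CoverageTrack", layout = layout, binSize = binSize,
      values = values, normState = normState)
}

#' @describeIn applyBlacklist drop intervals overlapping the blacklist.
setMethod("applyBlacklist", signature(x = "GRanges", layout = "GenomeLayout"),
  function(x, layout) {
    bl <- blacklist(layout)
    if (!length(bl) || !length(x)) return(x)
    hits <- GenomicRanges::countOverlaps(x, bl, ignore.strand = TRUE)
    x[hits == 0L]
  })

#' @describeIn applyBlacklist drop fragments overlapping the blacklist;
#'   spike-in count unchanged.
setMethod("applyBlacklist", signature(x = "FragmentSet", layout = "GenomeLayout"),
  function(x, layout) {
    new("FragmentSet", fragments = applyBlacklist(fragments(x), layout),
        spikeInCount = x@spikeInCount, libraryLabel = x@libraryLabel)
  })
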