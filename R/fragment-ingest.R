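# Paired-end alignment ingest: orientation filtering and the five-category
# coverage partition plus the signed fragment-termini track.

#' Classify the orientation of a read pair
#'
#' Looking 5' to 3' along the reference, the F read is the mate aligned to
#' the "+" strand and the R read the mate aligned to "-". Valid orientations
#' are `EQ` (mates span an identical interval), `FR` (left-most aligned base
#' shared or exclusive to the F read, right-most base exclusive to the R
#' read) and `SINGLE` (one mapped mate). `RF` (R read strictly left),
#' `TANDEM` (same strand) and `OTHER_INVALID` configurations are discarded
#' downstream as likely artifacts.
#'
#' @param span1,span2 0-based half-open alignment spans `c(start, end)` in
#'   window coordinates, or `NULL` for an unmapped mate.
#' @param strand1,strand2 Alignment strands, `"+"` or `"-"`.
#' @return One of `"EQ"`, `"FR"`, `"SINGLE"`, `"RF"`, `"TANDEM"`,
#'   `"OTHER_INVALID"`.
#' @examples
#' classifyPairOrientation(c(100, 250), "+", c(100, 250), "-")  # EQ
#' classifyPairOrientation(c(100, 250), "+", c(200, 350), "-")  # FR
#' classifyPairOrientation(c(200, 350), "+", c(100, 250), "-")  # RF
#' @export
classifyPairOrientation <- function(span1, strand1, span2, strand2) {
  if (is.null(span1) && is.null(span2))
    stop("both mates unmapped: not a pair")
  if (is.null(span1) || is.null(span2)) return("SINGLE")
  if (strand1 == strand2) return("TANDEM")
  f <- if (strand1 == "+") span1 else span2
  r <- if (strand1 == "+") span2 else span1
  if (f[1] == r[1] && f[2] == r[2]) return("EQ")
  if (r[1] < f[1]) return("RF")
  if (f[1] <= r[1] && r[2] > f[2]) return("FR")
  "OTHER_INVALID"
}

#' Load alignments from a SAM or BAM file
#'
#' SAM text is converted with [Rsamtools::asBam()] before reading; secondary
#' and supplementary alignments are dropped.
#'
#' @param path Path to a SAM or BAM file.
#' @return A `GAlignments` object with query names as names.
#' @export
readWindowAlignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  GenomicAlignments::readGAlignments(
    path, use.names = TRUE,
    param = Rsamtools::ScanBamParam(flag = flags, what = "flag"))
}

# Collapse a GAlignments object for one reference window into a per-pair list
# with spans, strands, soft-clip info, in window (0-based) coordinates.
collectPairs <- function(galn, locusId, windowLength) {
  keep <- as.character(GenomicAlignments::seqnames(galn)) == locusId
  galn <- galn[keep]
  if (length(galn) == 0L) return(list())
  cigars <- GenomicAlignments::cigar(galn)
  ops <- GenomicAlignments::explodeCigarOps(cigars)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigars)
  leftClip <- vapply(seq_along(ops), function(i) {
    if (length(ops[[i]]) && ops[[i]][1] == "S") lens[[i]][1] else 0L
  }, 0L)
  rightClip <- vapply(seq_along(ops), function(i) {
    k <- length(ops[[i]])
    if (k && ops[[i]][k] == "S") lens[[i]][k] else 0L
  }, 0L)
  starts <- GenomicAlignments::start(galn) - 1L
  ends <- GenomicAlignments::end(galn)
  strands <- as.character(GenomicAlignments::strand(galn))
  qnames <- names(galn)
  idx <- split(seq_along(galn), qnames)
  lapply(idx, function(i) {
    i <- i[seq_len(min(2L, length(i)))]
    mates <- lapply(i, function(j) {
      clips <- list()
      if (leftClip[j] > 0L)
        clips <- c(clips, list(c(max(0L, starts[j] - leftClip[j]), starts[j])))
      if (rightClip[j] > 0L)
        clips <- c(clips, list(c(ends[j], min(windowLength,
                                              ends[j] + rightClip[j]))))
      list(span = c(starts[j], ends[j]), strand = strands[j],
           softClipped = leftClip[j] > 0L || rightClip[j] > 0L,
           clipSpans = clips)
    })
    mates
  })
}

# Increment `vec` by one over the 0-based half-open interval [from, to),
# clipped to the vector bounds.
.incRange <- function(vec, from, to) {
  from <- max(0L, from)
  to <- min(length(vec), to)
  if (from < to) vec[(from + 1L):to] <- vec[(from + 1L):to] + 1L
  vec
}

#' Build the coverage profile for one locus and readset
#'
#' Accumulates the five coverage categories and the signed termini track from
#' orientation-filtered pairs. For a valid `EQ`/`FR` pair the fragment
#' termini are the left-most mapped base of the F read (counted -1 in the
#' signed track) and the right-most mapped base of the R read (+1); bases
#' mapped by both mates count as overlapped coverage, unmapped bases between
#' the mates as inferred coverage, soft-clip-covered bases as clipped
#' coverage, and remaining mapped bases as read coverage. Terminus positions
#' are excluded from the read/overlapped counts so the categories partition
#' the fragment depth at every base. Pairs with soft clips contribute no
#' termini unless `allowSoftClips`; single mapped mates contribute only
#' read/clipped coverage and only when `allowSingleReads`.
#'
#' @param alignments `GAlignments` from [readWindowAlignments()], or a path
#'   to a SAM/BAM file.
#' @param window A [ReferenceWindow-class].
#' @param readsetId,conditionId Identifiers recorded on the profile.
#' @param allowSingleReads,allowSoftClips Pair-handling flags (default both
#'   `FALSE`).
#' @param roi Optional 0-based half-open interval `c(from, to)`; when given,
#'   fragment-interval coverage is additionally split by whether the pair's
#'   R-read origin lies inside it (used by [plotLocusProfile()]).
#' @return A [CoverageProfile-class].
#' @export
buildCoverageProfile <- function(alignments, window, readsetId = "readset",
                                 conditionId = readsetId,
                                 allowSingleReads = FALSE,
                                 allowSoftClips = FALSE, roi = NULL) {
  if (is.character(alignments))
    alignments <- readWindowAlignments(alignments)
  n <- length(window@sequence)
  pairs <- collectPairs(alignments, window@locusId, n)
  zero <- integer(n)
  readCov <- zero; clipCov <- zero; overCov <- zero; infCov <- zero
  termCov <- zero; signed <- zero
  roiCov <- if (is.null(roi)) integer(0) else zero
  nonRoiCov <- if (is.null(roi)) integer(0) else zero
  counts <- c(EQ = 0L, FR = 0L, SINGLE = 0L, RF = 0L, TANDEM = 0L,
              OTHER_INVALID = 0L, SKIPPED = 0L)

  for (pair in pairs) {
    if (length(pair) == 1L) {
      counts["SINGLE"] <- counts["SINGLE"] + 1L
      if (!allowSingleReads) next
      m <- pair[[1]]
      readCov <- .incRange(readCov, m$span[1], m$span[2])
      for (cs in m$clipSpans) clipCov <- .incRange(clipCov, cs[1], cs[2])
      next
    }
    m1 <- pair[[1]]; m2 <- pair[[2]]
    orient <- classifyPairOrientation(m1$span, m1$strand, m2$span, m2$strand)
    counts[orient] <- counts[orient] + 1L
    if (!orient %in% c("EQ", "FR")) next
    f <- if (m1$strand == "+") m1 else m2
    r <- if (m1$strand == "+") m2 else m1
    hasClips <- f$softClipped || r$softClipped
    countTermini <- !hasClips || allowSoftClips
    tF <- f$span[1]
    tR <- r$span[2] - 1L
    if (countTermini && (tF < 0L || tF >= n || tR < 0L || tR >= n)) {
      counts["SKIPPED"] <- counts["SKIPPED"] + 1L
      next
    }
    if (countTermini) {
      signed[tF + 1L] <- signed[tF + 1L] - 1L
      signed[tR + 1L] <- signed[tR + 1L] + 1L
      termCov[tF + 1L] <- termCov[tF + 1L] + 1L
      termCov[tR + 1L] <- termCov[tR + 1L] + 1L
    }
    # Partition the fragment interval [f5, r3): both-mate bases are
    # overlapped, single-mate bases read, gap bases inferred; counted termini
    # are removed from read/overlapped so nothing is double counted.
    f5 <- f$span[1]; r3 <- r$span[2]
    ovFrom <- max(f$span[1], r$span[1]); ovTo <- min(f$span[2], r$span[2])
    fOnly <- c(f$span[1], min(f$span[2], r$span[1]))   # F-exclusive bases
    rOnly <- c(max(r$span[1], f$span[2]), r$span[2])   # R-exclusive bases
    gap <- c(f$span[2], r$span[1])                     # unmapped between mates
    if (countTermini) {
      # tF == f5 is the first base of either the F-only run or the overlap;
      # tR == r3 - 1 the last base of the R-only run or the overlap.
      if (fOnly[1] < fOnly[2]) fOnly[1] <- fOnly[1] + 1L
      else ovFrom <- ovFrom + 1L
      if (rOnly[1] < rOnly[2]) rOnly[2] <- rOnly[2] - 1L
      else ovTo <- ovTo - 1L
    }
    readCov <- .incRange(readCov, fOnly[1], fOnly[2])
    readCov <- .incRange(readCov, rOnly[1], rOnly[2])
    overCov <- .incRange(overCov, ovFrom, ovTo)
    infCov <- .incRange(infCov, gap[1], gap[2])
    for (cs in f$clipSpans) clipCov <- .incRange(clipCov, cs[1], cs[2])
    for (cs in r$clipSpans) clipCov <- .incRange(clipCov, cs[1], cs[2])
    if (!is.null(roi)) {
      inRoi <- tR >= roi[1] && tR < roi[2]
      if (inRoi) roiCov <- .incRange(roiCov, f5, r3)
      else nonRoiCov <- .incRange(nonRoiCov, f5, r3)
    }
  }

  new("CoverageProfile", locusId = window@locusId, readsetId = readsetId,
      conditionId = conditionId, readCoverage = readCov,
      clippedCoverage = clipCov, overlappedCoverage = overCov,
      inferredCoverage = infCov, terminiCoverage = termCov,
      signedTermini = signed, roiCoverage = roiCov,
      nonRoiCoverage = nonRoiCov,
      riboswitchStart = window@riboswitchStart,
      riboswitchEnd = window@riboswitchEnd, nPairs = counts)
}

#' Minimum-depth filter for a locus/readset profile
#'
#' A locus is analyzed under a readset only when the mean total coverage
#' across the riboswitch reaches `minCovDepth` (default 15).
#'
#' @param profile A [CoverageProfile-class].
#' @param minCovDepth Depth threshold.
#' @return `TRUE` when the profile passes.
#' @export
passesDepthFilter <- function(profile, minCovDepth = 15) {
  meanRiboswitchCoverage(profile) >= minCovDepth
}
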