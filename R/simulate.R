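# Ground-truthed synthetic data: ON/OFF transcript pools, biased
# fragmentation with paired neighboring termini, and paired-end SAM output.

#' Simulated reference for a synthetic riboswitch locus
#'
#' Generates a random-sequence contig carrying the programmed riboswitch and
#' builds the oriented [ReferenceWindow-class] (here the whole contig, since
#' the simulated neighborhood is the experiment). The reference depends only
#' on the spec's seed, never on how many readsets are drawn.
#'
#' @param spec A [SimulationSpec-class].
#' @return List with `window` (a [ReferenceWindow-class]), `loci` (a
#'   one-row locus table in contig coordinates) and `truth` (a one-row
#'   `data.frame` of the programmed terminator and per-condition
#'   efficiencies).
#' @export
makeSimulatedReference <- function(spec) {
  seq <- withPrivateSeedValue(spec@seed, paste(
    sample(c("A", "C", "G", "T"), spec@windowLength, replace = TRUE),
    collapse = ""))
  locusId <- sprintf("synthetic_locus_seed%d", spec@seed)
  loci <- data.frame(locus_id = locusId, contig_id = locusId,
                     family = "synthetic",
                     source_start = spec@riboswitchStart,
                     source_end = spec@riboswitchEnd, strand = "+",
                     model_score = NA_real_, e_value = NA_real_,
                     stringsAsFactors = FALSE)
  window <- buildReferenceWindow(loci[1, ], Biostrings::DNAString(seq),
                                 flank = spec@windowLength)
  truth <- cbind(
    data.frame(locus_id = locusId,
               terminator_position = spec@terminatorPosition,
               relative_terminator_position =
                 (spec@terminatorPosition - spec@riboswitchEnd) /
                 (spec@riboswitchEnd - spec@riboswitchStart),
               stringsAsFactors = FALSE),
    stats::setNames(
      as.data.frame(t(spec@conditions$termination_efficiency)),
      paste0("efficiency_", spec@conditions$condition_id)))
  list(window = window, loci = loci, truth = truth)
}

withPrivateSeedValue <- function(seed, code) {
  out <- NULL
  withPrivateSeed(seed, out <- force(code))
  out
}

#' Simulate a transcript pool for one condition
#'
#' Every transcript starts at the TSS. With probability equal to the
#' condition's termination efficiency it ends at the programmed terminator
#' position plus rounded Gaussian jitter; otherwise it reads through to the
#' window end.
#'
#' @param spec A [SimulationSpec-class].
#' @param conditionId Condition to simulate.
#' @param nTranscripts Optional override of the per-readset transcript count.
#' @return `data.frame` with columns `start`, `end` (0-based half-open) and
#'   `terminated`.
#' @export
simulateTranscripts <- function(spec, conditionId, nTranscripts = NULL) {
  row <- spec@conditions[spec@conditions$condition_id == conditionId, ]
  if (nrow(row) != 1L) stop("unknown condition: ", conditionId)
  n <- if (is.null(nTranscripts)) row$n_transcripts else nTranscripts
  terminated <- stats::runif(n) < row$termination_efficiency
  ends <- ifelse(
    terminated,
    pmin(spec@windowLength,
         pmax(spec@tssPosition + 1L,
              spec@terminatorPosition +
                round(stats::rnorm(n, 0, spec@terminatorJitterSd)))),
    spec@windowLength)
  data.frame(start = spec@tssPosition, end = as.integer(ends),
             terminated = terminated)
}

# Truncated-lognormal fragment lengths, by rejection.
.rfraglen <- function(n, spec) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(max(n, 16L), spec@fragMeanlog, spec@fragSdlog)
    out <- c(out, x[x >= spec@minFrag & x <= spec@maxFrag])
  }
  round(out[seq_len(n)])
}

#' Fragment transcripts and derive paired-end read spans
#'
#' Each transcript is cut left to right at breakpoints spaced by
#' truncated-lognormal fragment lengths, so every internal breakpoint is
#' shared between the 3' end of one fragment and the 5' end of the next
#' (the neighboring-termini property that the convolution cancels). The
#' final remainder fragment (carrying the transcript 3' end) is retained.
#' Each fragment yields an F read over its first `readLength` bases and an
#' R read over its last `readLength` bases; fragments no longer than a read
#' give an EQ pair spanning the whole fragment.
#'
#' @param transcripts `data.frame` from [simulateTranscripts()].
#' @param spec A [SimulationSpec-class].
#' @return `data.frame` with columns `frag_start`, `frag_end`, `f_start`,
#'   `f_end`, `r_start`, `r_end` (0-based half-open) and `is_transcript_3p`.
#' @export
fragmentAndPair <- function(transcripts, spec) {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    s <- transcripts$start[i]; e <- transcripts$end[i]
    len <- e - s
    draws <- .rfraglen(max(2L, ceiling(len / spec@minFrag)), spec)
    while (sum(draws) < len) draws <- c(draws, .rfraglen(4L, spec))
    bounds <- s + cumsum(draws)
    bounds <- c(s, bounds[bounds < e], e)
    data.frame(frag_start = bounds[-length(bounds)],
               frag_end = bounds[-1],
               is_transcript_3p = seq_len(length(bounds) - 1L) ==
                 length(bounds) - 1L)
  })
  frags <- do.call(rbind, rows)
  flen <- frags$frag_end - frags$frag_start
  rl <- spec@readLength
  frags$f_start <- frags$frag_start
  frags$f_end <- ifelse(flen <= rl, frags$frag_end, frags$frag_start + rl)
  frags$r_start <- ifelse(flen <= rl, frags$frag_start, frags$frag_end - rl)
  frags$r_end <- frags$frag_end
  frags
}

#' Write a simulated readset as SAM
#'
#' Emits one properly-paired FR (or EQ) alignment pair per fragment against
#' the simulated window reference, with 1-based positions, full-match
#' CIGARs, and reference-derived sequences (the R read is stored
#' reverse-complemented, as in a real alignment). Output is deterministic
#' given the pair table.
#'
#' @param pairs `data.frame` from [fragmentAndPair()].
#' @param window The simulated [ReferenceWindow-class].
#' @param readsetId Readset identifier (used in read names).
#' @param samPath Output path.
#' @return `samPath`, invisibly.
#' @export
writeSimulatedSam <- function(pairs, window, readsetId, samPath) {
  refName <- window@locusId
  refLen <- length(window@sequence)
  refSeq <- as.character(window@sequence)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", refName, refLen))
  if (nrow(pairs) > 0L) {
    qname <- sprintf("%s_frag%06d", readsetId, seq_len(nrow(pairs)))
    fLen <- pairs$f_end - pairs$f_start
    rLen <- pairs$r_end - pairs$r_start
    tlen <- pairs$frag_end - pairs$frag_start
    fSeq <- substring(refSeq, pairs$f_start + 1L, pairs$f_end)
    rSeq <- vapply(substring(refSeq, pairs$r_start + 1L, pairs$r_end),
                   function(s) as.character(
                     Biostrings::reverseComplement(Biostrings::DNAString(s))),
                   "", USE.NAMES = FALSE)
    fLine <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
                     qname, refName, pairs$f_start + 1L, fLen,
                     pairs$r_start + 1L, tlen, fSeq,
                     strrep("I", fLen))
    rLine <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
                     qname, refName, pairs$r_start + 1L, rLen,
                     pairs$f_start + 1L, -tlen, rSeq,
                     strrep("I", rLen))
    lines <- c(lines, as.vector(rbind(fLine, rLine)))
  }
  writeLines(lines, samPath)
  invisible(samPath)
}

#' Simulate a complete multi-condition dataset on disk
#'
#' Writes the reference FASTA, the locus and truth tables, and one SAM file
#' per readset of every condition, all deterministic under the spec's seed.
#'
#' @param spec A [SimulationSpec-class].
#' @param dir Output directory (created if needed).
#' @return List with `window`, `loci`, `truth`, and `manifest` (a
#'   `data.frame` mapping `readset_id` and `condition_id` to SAM paths plus
#'   the reference file paths).
#' @export
simulateDataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- makeSimulatedReference(spec)
  fastaPath <- file.path(dir, "reference.fasta")
  tsvPath <- file.path(dir, "reference_windows.tsv")
  writeReferenceWindows(list(ref$window), fastaPath, tsvPath)
  utils::write.table(ref$loci, file.path(dir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ref$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- NULL
  for (ci in seq_len(nrow(spec@conditions))) {
    cond <- spec@conditions$condition_id[ci]
    for (ri in seq_len(spec@conditions$n_readsets[ci])) {
      readsetId <- sprintf("%s_rep%d", cond, ri)
      samPath <- file.path(dir, paste0(readsetId, ".sam"))
      withPrivateSeed(spec@seed + 7901L * ci + 13L * ri, {
        tx <- simulateTranscripts(spec, cond)
        pairs <- fragmentAndPair(tx, spec)
        writeSimulatedSam(pairs, ref$window, readsetId, samPath)
      })
      manifest <- rbind(manifest, data.frame(
        readset_id = readsetId, condition_id = cond, sam = samPath,
        stringsAsFactors = FALSE))
    }
  }
  manifestFile <- manifest
  manifestFile$sam <- basename(manifestFile$sam)  # keep the file relocatable
  utils::write.table(manifestFile, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(window = ref$window, loci = ref$loci, truth = ref$truth,
       manifest = manifest)
}
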