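# Locus discovery parsing and oriented reference-window construction.
#
# All coordinates inside the package are 0-based half-open; conversion from
# the 1-based inclusive conventions of Infernal and Prodigal happens here, at
# the parser boundary, and nowhere else.

#' Parse Infernal cmscan tabular output into a riboswitch locus table
#'
#' Reads the whitespace-separated `--tblout` format: one hit per
#' non-comment line, with the covariance-model name in column 1, the query
#' sequence in column 3, 1-based inclusive sequence coordinates in columns 8
#' and 9 (reversed for minus-strand hits) and the strand in column 10.
#'
#' @param path Path to a cmscan tblout file.
#' @return A locus `data.frame` with columns `locus_id`, `contig_id`,
#'   `family`, `source_start`, `source_end` (0-based half-open, always
#'   `start < end`), `strand`, `model_score`, `e_value`. Overlapping hits from
#'   different models are all retained as distinct loci.
#' @examples
#' tbl <- tempfile(fileext = ".tblout")
#' writeLines(c(
#'   "#target name accession query name accession mdl mdl from mdl to seq from seq to strand trunc pass gc bias score E-value inc description",
#'   "TPP - contig1 - cm 1 105 100 250 + no 1 0.45 0.0 55.2 1.1e-10 ! -"
#' ), tbl)
#' parseCmscanTblout(tbl)
#' @export
parseCmscanTblout <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hits <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(hits) == 0L) {
    warning("no hits in tblout file ", path)
    return(emptyLocusTable())
  }
  rows <- lapply(seq_along(hits), function(i) {
    f <- strsplit(trimws(hits[i]), "[ \t]+")[[1]]
    lineNo <- which(lines == hits[i])[1]
    if (length(f) < 17L)
      stop("malformed tblout line ", lineNo, ": expected >= 17 fields, got ",
           length(f))
    from <- suppressWarnings(as.numeric(f[8]))
    to <- suppressWarnings(as.numeric(f[9]))
    strand <- f[10]
    if (is.na(from) || is.na(to) || !strand %in% c("+", "-"))
      stop("malformed tblout line ", lineNo,
           ": bad coordinates or strand field")
    # Infernal reports 1-based inclusive coordinates; minus-strand hits have
    # seq-from > seq-to. Normalise to 0-based half-open with start < end.
    lo <- min(from, to)
    hi <- max(from, to)
    data.frame(contig_id = f[3], family = f[1],
               source_start = lo - 1, source_end = hi, strand = strand,
               model_score = suppressWarnings(as.numeric(f[15])),
               e_value = suppressWarnings(as.numeric(f[16])),
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, rows)
  loci$locus_id <- make.unique(sprintf("%s_%s_%d%s", loci$family,
                                       loci$contig_id, loci$source_start,
                                       loci$strand), sep = "_")
  loci[, locusTableColumns()]
}

locusTableColumns <- function() {
  c("locus_id", "contig_id", "family", "source_start", "source_end",
    "strand", "model_score", "e_value")
}

emptyLocusTable <- function() {
  df <- data.frame(locus_id = character(0), contig_id = character(0),
                   family = character(0), source_start = numeric(0),
                   source_end = numeric(0), strand = character(0),
                   model_score = numeric(0), e_value = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

#' Read a plain TSV locus table
#'
#' Accepts precomputed riboswitch coordinates so the pipeline can run without
#' Infernal. Expected columns: `locus_id`, `contig_id` (or `contig`),
#' `source_start`/`start`, `source_end`/`end` (0-based half-open), `strand`,
#' `family`; `model_score` and `e_value` are optional.
#'
#' @param path Path to a tab-separated table with a header line.
#' @return A locus `data.frame` as from [parseCmscanTblout()].
#' @export
readLocusTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  alias <- c(contig = "contig_id", start = "source_start", end = "source_end")
  for (a in names(alias))
    if (a %in% names(df) && !alias[[a]] %in% names(df))
      names(df)[names(df) == a] <- alias[[a]]
  need <- c("locus_id", "contig_id", "source_start", "source_end", "strand",
            "family")
  if (!all(need %in% names(df)))
    stop("locus table ", path, " must provide columns: ",
         paste(need, collapse = ", "))
  if (!"model_score" %in% names(df)) df$model_score <- NA_real_
  if (!"e_value" %in% names(df)) df$e_value <- NA_real_
  stopifnot(all(df$source_start < df$source_end),
            all(df$strand %in% c("+", "-")),
            !anyDuplicated(df$locus_id))
  df[, locusTableColumns()]
}

#' Parse ORF predictions
#'
#' `parseOrfGff()` reads Prodigal (or any) GFF gene calls via
#' `rtracklayer`; `parseProdigalFastaHeaders()` reads the coordinates that
#' Prodigal embeds in its protein/nucleotide FASTA headers
#' (`>id # start # end # strand # ...`).
#'
#' @param path Path to a GFF file or Prodigal FASTA file.
#' @return A `data.frame` with columns `orf_id`, `contig_id`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
parseOrfGff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff")
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("orf_%d", seq_along(gr))
  data.frame(orf_id = ids,
             contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname parseOrfGff
#' @export
parseProdigalFastaHeaders <- function(path) {
  lines <- grep("^>", readLines(path), value = TRUE)
  if (length(lines) == 0L)
    return(data.frame(orf_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(sub("^>", "", lines), " # ")
  bad <- which(lengths(parts) < 4L)
  if (length(bad))
    stop("malformed Prodigal FASTA header at entry ", bad[1])
  ids <- vapply(parts, `[[`, "", 1L)
  data.frame(orf_id = ids,
             contig_id = sub("_[0-9]+$", "", ids),
             start = as.integer(vapply(parts, `[[`, "", 2L)) - 1L,
             end = as.integer(vapply(parts, `[[`, "", 3L)),
             strand = ifelse(vapply(parts, `[[`, "", 4L) == "1", "+", "-"),
             stringsAsFactors = FALSE)
}

#' Assign the downstream ORF to a riboswitch locus
#'
#' The downstream gene is the first same-strand ORF past the riboswitch 5'
#' end, reading in the riboswitch's direction; ORFs that overlap the
#' riboswitch qualify. For a "+" locus this is the same-strand ORF with the
#' smallest start not before the riboswitch start; for a "-" locus, the ORF
#' with the largest end not after the riboswitch end.
#'
#' @param locus One row of a locus table (list or single-row `data.frame`).
#' @param orfs ORF `data.frame` as from [parseOrfGff()].
#' @return The matching ORF row, or `NULL` when no same-strand ORF qualifies.
#' @export
assignDownstreamOrf <- function(locus, orfs) {
  cand <- orfs[orfs$contig_id == locus$contig_id &
                 orfs$strand == locus$strand, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  if (locus$strand == "+") {
    cand <- cand[cand$start >= locus$source_start, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[which.min(cand$start), , drop = FALSE]
  } else {
    cand <- cand[cand$end <= locus$source_end, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand[which.max(cand$end), , drop = FALSE]
  }
}

#' Build an oriented reference window around a riboswitch
#'
#' Trims the source contig to `[source_start - flank, source_end + flank)`,
#' clipped at the contig ends (windows near contig boundaries are smaller or
#' asymmetric). Windows for minus-strand loci are reverse complemented so the
#' riboswitch always reads 5' to 3', and riboswitch bounds are re-expressed in
#' the window frame.
#'
#' @param locus One row of a locus table.
#' @param contigSequence [Biostrings::DNAString] (or coercible string) of the
#'   source contig.
#' @param flank Flank size in nt (default 1000).
#' @return A [ReferenceWindow-class].
#' @export
buildReferenceWindow <- function(locus, contigSequence, flank = 1000) {
  if (!is(contigSequence, "DNAString"))
    contigSequence <- Biostrings::DNAString(contigSequence)
  len <- length(contigSequence)
  if (locus$source_start < 0 || locus$source_end > len)
    stop("locus ", locus$locus_id, " lies outside contig ", locus$contig_id,
         " (length ", len, ")")
  wstart <- max(0, locus$source_start - flank)
  wend <- min(len, locus$source_end + flank)
  seq <- Biostrings::subseq(contigSequence, wstart + 1L, wend)
  if (locus$strand == "-") {
    seq <- Biostrings::reverseComplement(seq)
    rsStart <- wend - locus$source_end
    rsEnd <- wend - locus$source_start
  } else {
    rsStart <- locus$source_start - wstart
    rsEnd <- locus$source_end - wstart
  }
  new("ReferenceWindow", locusId = locus$locus_id,
      family = if (is.null(locus$family) || is.na(locus$family)) "unknown"
               else locus$family,
      sequence = seq, contigId = locus$contig_id,
      windowStartOnContig = as.integer(wstart),
      riboswitchStart = as.integer(rsStart), riboswitchEnd = as.integer(rsEnd),
      strand = locus$strand,
      wasReverseComplemented = locus$strand == "-")
}

#' Build reference windows for every locus in a table
#'
#' @param loci Locus `data.frame` (see [parseCmscanTblout()]).
#' @param contigs Named [Biostrings::DNAStringSet] (or named character vector)
#'   of source contigs.
#' @param flank Flank size in nt.
#' @return Named list of [ReferenceWindow-class] objects, one per locus.
#' @export
buildReferenceWindows <- function(loci, contigs, flank = 1000) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  out <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    if (!locus$contig_id %in% names(contigs))
      stop("no contig sequence for locus ", locus$locus_id)
    buildReferenceWindow(locus, contigs[[locus$contig_id]], flank)
  })
  names(out) <- loci$locus_id
  out
}

#' Write and re-read reference windows
#'
#' `writeReferenceWindows()` saves the per-locus reference FASTA (sequences
#' named by locus id) plus a metadata TSV holding the window-frame riboswitch
#' bounds; `readReferenceWindows()` restores the windows from those files.
#'
#' @param windows List of [ReferenceWindow-class] objects.
#' @param fastaPath,tsvPath Output (or input) file paths.
#' @return `writeReferenceWindows()` returns the paths invisibly;
#'   `readReferenceWindows()` returns a named list of windows.
#' @export
writeReferenceWindows <- function(windows, fastaPath, tsvPath) {
  seqs <- Biostrings::DNAStringSet(lapply(windows, slot, "sequence"))
  names(seqs) <- vapply(windows, slot, "", "locusId")
  Biostrings::writeXStringSet(seqs, fastaPath)
  meta <- do.call(rbind, lapply(windows, function(w) {
    data.frame(locus_id = w@locusId, family = w@family,
               contig_id = w@contigId,
               window_start_on_contig = w@windowStartOnContig,
               riboswitch_start = w@riboswitchStart,
               riboswitch_end = w@riboswitchEnd, strand = w@strand,
               was_reverse_complemented = w@wasReverseComplemented,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(meta, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fastaPath, tsv = tsvPath))
}

#' @rdname writeReferenceWindows
#' @export
readReferenceWindows <- function(fastaPath, tsvPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    new("ReferenceWindow", locusId = m$locus_id, family = m$family,
        sequence = seqs[[m$locus_id]], contigId = m$contig_id,
        windowStartOnContig = as.integer(m$window_start_on_contig),
        riboswitchStart = as.integer(m$riboswitch_start),
        riboswitchEnd = as.integer(m$riboswitch_end), strand = m$strand,
        wasReverseComplemented = as.logical(m$was_reverse_complemented))
  })
  names(out) <- meta$locus_id
  out
}
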