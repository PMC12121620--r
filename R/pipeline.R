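# End-to-end orchestration: ingest -> convolution -> peak calls ->
# cross-condition cluster statistics -> tabular and graphical outputs.

#' Run the termination-detection pipeline
#'
#' For every reference window and readset this builds the coverage profile,
#' applies the depth filter, convolves the signed termini track, detects and
#' scores peaks against the per-locus noise model, then clusters all peaks
#' inside the region of interest across conditions and applies the
#' mean/variance cluster tests to produce a per-locus verdict.
#'
#' @param windows Named list of [ReferenceWindow-class] objects (or a length-2
#'   character vector `c(fasta, tsv)` accepted by [readReferenceWindows()]).
#' @param manifest `data.frame` with columns `readset_id`, `condition_id`,
#'   `sam` (paths to SAM/BAM alignments against the windows).
#' @param config A [PipelineConfig-class].
#' @param outDir Output directory for `peak_log.csv`, `cluster_stats.csv`,
#'   `locus_verdicts.csv` and plots; `NULL` skips all file output.
#' @param plots Whether to render locus and peak plots (requires `outDir`).
#' @return Invisibly, a list with `peakLog`, `clusterStats`, `verdicts` and
#'   `profiles` (nested list by locus then readset).
#' @export
runPipeline <- function(windows, manifest, config = pipelineConfig(),
                        outDir = NULL, plots = !is.null(outDir)) {
  if (is.character(windows) && length(windows) == 2L)
    windows <- readReferenceWindows(windows[1], windows[2])
  stopifnot(all(c("readset_id", "condition_id", "sam") %in% names(manifest)),
            nrow(manifest) >= 1L)
  alignments <- lapply(manifest$sam, readWindowAlignments)
  names(alignments) <- manifest$readset_id

  peakLog <- NULL
  clusterStats <- NULL
  verdicts <- NULL
  profiles <- list()
  convTracks <- list()

  for (w in windows) {
    roi <- regionOfInterest(w@riboswitchStart, w@riboswitchEnd,
                            config@roiHalfWidthProp)
    locusPeaks <- NULL
    locusProfiles <- list()
    locusConv <- list()
    depthPass <- logical(0)
    for (i in seq_len(nrow(manifest))) {
      rid <- manifest$readset_id[i]
      profile <- buildCoverageProfile(
        alignments[[rid]], w, readsetId = rid,
        conditionId = manifest$condition_id[i],
        allowSingleReads = config@allowSingleReads,
        allowSoftClips = config@allowSoftClips, roi = roi)
      locusProfiles[[rid]] <- profile
      ok <- passesDepthFilter(profile, config@minCovDepth)
      depthPass[rid] <- ok
      if (!ok) next
      conv <- convolveSignedTermini(
        signedTermini(profile),
        gaussianKernel(config@sigma, config@kernelHalfWidth))
      locusConv[[rid]] <- conv
      peaks <- detectPeaks(conv, config@zeroBand)
      calls <- callPeaks(peaks, profile, config)
      locusPeaks <- rbind(locusPeaks, calls)
    }
    profiles[[w@locusId]] <- locusProfiles
    convTracks[[w@locusId]] <- locusConv

    inRoi <- if (is.null(locusPeaks)) NULL else
      locusPeaks[locusPeaks$summit >= roi[1] & locusPeaks$summit < roi[2], ,
                 drop = FALSE]
    clustered <- if (is.null(inRoi) || nrow(inRoi) == 0L) {
      df <- if (is.null(inRoi)) data.frame() else inRoi
      df$cluster <- integer(nrow(df))
      df
    } else clusterPeaks(inRoi, config@copheneticThreshold)

    conditions <- unique(manifest$condition_id)
    conditionStates <- vapply(conditions, function(cond) {
      !is.null(locusPeaks) &&
        any(locusPeaks$decision == "pass" &
              locusPeaks$condition_id == cond)
    }, FALSE)
    call <- callLocus(clustered, w@locusId, w@family,
                      conditionStates = conditionStates,
                      anyDepthPass = any(depthPass), config = config)
    if (!is.null(locusPeaks)) {
      locusPeaks$family <- w@family
      # record cluster membership in the peak log
      locusPeaks$cluster <- NA_integer_
      if (nrow(clustered) > 0L) {
        key <- paste(clustered$readset_id, clustered$summit)
        m <- match(paste(locusPeaks$readset_id, locusPeaks$summit), key)
        locusPeaks$cluster <- clustered$cluster[m]
      }
      peakLog <- rbind(peakLog, locusPeaks)
    }
    clusterStats <- rbind(clusterStats, call$clusters)
    verdicts <- rbind(verdicts, call$verdict)

    if (plots && !is.null(outDir)) {
      for (rid in names(locusProfiles)) {
        if (!depthPass[rid]) next
        sub <- if (is.null(locusPeaks)) emptyPeakLog() else
          locusPeaks[locusPeaks$readset_id == rid, , drop = FALSE]
        passDir <- if (nrow(sub) > 0L && any(sub$decision == "pass"))
          "pass" else "fail"
        pdir <- file.path(outDir, "locus_plots", passDir)
        dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
        grDevices::png(file.path(pdir, sprintf("%s__%s.png", w@locusId, rid)),
                       width = 900, height = 700)
        plotLocusProfile(locusProfiles[[rid]], locusConv[[rid]], sub)
        grDevices::dev.off()
      }
      pdir <- file.path(outDir, "peak_plots")
      dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
      grDevices::png(file.path(pdir, sprintf("%s.png", w@locusId)),
                     width = 800, height = 600)
      plotPeakSummary(clustered, call$clusters, w)
      grDevices::dev.off()
    }
  }

  if (is.null(peakLog)) peakLog <- emptyPeakLog()
  if (is.null(clusterStats))
    clusterStats <- callLocus(data.frame(), "none")$clusters[0, ]
  out <- list(peakLog = peakLog, clusterStats = clusterStats,
              verdicts = verdicts, profiles = profiles,
              convTracks = convTracks)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writePeakLog(peakLog, file.path(outDir, "peak_log.csv"))
    writeClusterStats(clusterStats, verdicts, outDir)
  }
  invisible(out)
}

emptyPeakLog <- function() {
  data.frame(summit = integer(0), left_bound = integer(0),
             right_bound = integer(0), amplitude = numeric(0),
             width = integer(0), sign = character(0),
             locus_id = character(0), readset_id = character(0),
             condition_id = character(0), relative_position = numeric(0),
             coverage_drop = numeric(0), in_noise_region = logical(0),
             noise_n = integer(0), noise_mean_width = numeric(0),
             noise_mean_amp = numeric(0), pseudo_p = numeric(0),
             decision = character(0), fail_reason = character(0),
             family = character(0), cluster = integer(0),
             stringsAsFactors = FALSE)
}

#' Write the per-peak log
#'
#' One row per candidate convolution peak across all loci, readsets and
#' conditions, including shape, relative position, fractional coverage
#' change, noise-model parameters, pseudo p-value, and the pass/fail call
#' with its reason.
#'
#' @param peakLog Peak frame from [runPipeline()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writePeakLog <- function(peakLog, path) {
  cols <- c("locus_id", "family", "readset_id", "condition_id", "summit",
            "left_bound", "right_bound", "width", "amplitude", "sign",
            "relative_position", "coverage_drop", "in_noise_region",
            "noise_n", "noise_mean_width", "noise_mean_amp", "pseudo_p",
            "cluster", "decision", "fail_reason")
  cols <- cols[cols %in% names(peakLog)]
  utils::write.csv(peakLog[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Write cluster statistics and locus verdicts
#'
#' @param clusterStats Cluster frame from [runPipeline()].
#' @param verdicts Per-locus verdict frame.
#' @param outDir Output directory; writes `cluster_stats.csv` and
#'   `locus_verdicts.csv`.
#' @return The two paths, invisibly.
#' @export
writeClusterStats <- function(clusterStats, verdicts, outDir) {
  p1 <- file.path(outDir, "cluster_stats.csv")
  p2 <- file.path(outDir, "locus_verdicts.csv")
  utils::write.csv(clusterStats, p1, row.names = FALSE)
  utils::write.csv(verdicts, p2, row.names = FALSE)
  invisible(c(clusters = p1, verdicts = p2))
}

#' Run one seeded synthetic validation experiment
#'
#' Simulates the standard two-condition synthetic dataset (termination
#' efficiencies `efficiencyA`/`efficiencyB`, `nReadsets` readsets per
#' condition, about `nTranscripts`x riboswitch depth) under one seed, runs
#' the full pipeline on the emitted SAM files, and summarizes recovery of
#' the programmed terminator.
#'
#' @param seed Integer seed for the simulation.
#' @param efficiencyA,efficiencyB Per-condition termination efficiencies.
#' @param nReadsets,nTranscripts Readsets per condition and transcripts per
#'   readset.
#' @param config A [PipelineConfig-class].
#' @param dir Working directory for the simulated files (removed afterwards
#'   when `cleanup` is `TRUE`).
#' @param cleanup Remove the simulated files when done.
#' @return List with `verdict`, `truthPosition` (programmed terminator in
#'   relative units), `significantCentroids`, `centroidError` (smallest
#'   absolute centroid error among significant clusters, `Inf` when none),
#'   `nSignificant`, and the full pipeline `result`.
#' @export
runSyntheticExperiment <- function(seed, efficiencyA = 0.9,
                                   efficiencyB = 0.1, nReadsets = 4L,
                                   nTranscripts = 60L,
                                   config = pipelineConfig(),
                                   dir = tempfile("riboterm_sim"),
                                   cleanup = TRUE) {
  spec <- simulationSpec(seed = seed, conditions = data.frame(
    condition_id = c("A", "B"), n_readsets = as.integer(nReadsets),
    n_transcripts = as.integer(nTranscripts),
    termination_efficiency = c(efficiencyA, efficiencyB),
    stringsAsFactors = FALSE))
  sim <- simulateDataset(spec, dir)
  if (cleanup) on.exit(unlink(dir, recursive = TRUE))
  res <- runPipeline(list(sim$window), sim$manifest, config = config,
                     outDir = NULL, plots = FALSE)
  sig <- res$clusterStats[res$clusterStats$decision == "significant", ,
                          drop = FALSE]
  truthPos <- sim$truth$relative_terminator_position
  err <- if (nrow(sig)) min(abs(sig$centroid - truthPos)) else Inf
  list(verdict = res$verdicts$verdict, truthPosition = truthPos,
       significantCentroids = sig$centroid, centroidError = err,
       nSignificant = nrow(sig), result = res)
}
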