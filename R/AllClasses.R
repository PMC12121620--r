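#' @import methods
#' @importClassesFrom Biostrings DNAString
NULL

#' Pipeline configuration
#'
#' Holds every tunable of the termination-detection pipeline. The defaults are
#' the method's standard operating point: 1,000-nt reference flanks, a mean
#' riboswitch read depth of at least 15x, a 51-element Gaussian kernel with
#' sigma = 1.5, a convolution zero band of (-0.1, 0.1), a noise-set region
#' spanning the last 70% of the riboswitch plus one riboswitch length
#' downstream (`extProp = c(-0.3, 1.0)`), a region of interest of +/- 0.5x
#' riboswitch size around the 3' end, a minimum fractional coverage drop of
#' 20%, alpha = 0.05 for the peak, mean and variance tests, complete-linkage
#' clustering cut at cophenetic distance 0.04, and at least 60 resampled
#' Levene comparisons.
#'
#' @slot flank integer, nt of genomic context kept on each side of a riboswitch.
#' @slot minCovDepth numeric, minimum mean total coverage across the riboswitch.
#' @slot sigma numeric, standard deviation (nt) of the Gaussian kernel.
#' @slot kernelHalfWidth integer, kernel half width; the kernel has
#'   `2 * kernelHalfWidth + 1` elements.
#' @slot zeroBand numeric, half-width of the open zero region of the
#'   convolution amplitude.
#' @slot extProp numeric length-2, proportions of riboswitch size by which the
#'   noise-set region extends past the 5' and 3' riboswitch ends (negative
#'   first element trims into the riboswitch).
#' @slot roiHalfWidthProp numeric, region-of-interest half width as a
#'   proportion of riboswitch size, centred on the riboswitch 3' end.
#' @slot minDrop numeric, minimum fractional coverage drop for a termination
#'   call (0.20 means a drop of at least 20% of mean locus coverage).
#' @slot alphaPeak,alphaMean,alphaVariance numeric significance thresholds.
#' @slot copheneticThreshold numeric, complete-linkage flat-cluster cut on
#'   relative peak positions.
#' @slot nLeveneComparisons integer, minimum number of resampled Levene tests.
#' @slot minNoiseSet integer, minimum peaks needed to fit the noise model.
#' @slot allowSingleReads logical, count pairs with one unmapped mate.
#' @slot allowSoftClips logical, let soft-clipped pairs contribute termini.
#' @slot seed integer, seed for the Levene resampling RNG.
#' @export
setClass("PipelineConfig", representation(
  flank = "numeric",
  minCovDepth = "numeric",
  sigma = "numeric",
  kernelHalfWidth = "integer",
  zeroBand = "numeric",
  extProp = "numeric",
  roiHalfWidthProp = "numeric",
  minDrop = "numeric",
  alphaPeak = "numeric",
  alphaMean = "numeric",
  alphaVariance = "numeric",
  copheneticThreshold = "numeric",
  nLeveneComparisons = "integer",
  minNoiseSet = "integer",
  allowSingleReads = "logical",
  allowSoftClips = "logical",
  seed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character(0)
  pos <- c(
    flank = object@flank, minCovDepth = object@minCovDepth,
    sigma = object@sigma, kernelHalfWidth = object@kernelHalfWidth,
    zeroBand = object@zeroBand, minDrop = object@minDrop,
    copheneticThreshold = object@copheneticThreshold,
    nLeveneComparisons = object@nLeveneComparisons,
    minNoiseSet = object@minNoiseSet
  )
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "flank, minCovDepth, sigma, kernelHalfWidth, zeroBand, minDrop, copheneticThreshold, nLeveneComparisons and minNoiseSet must be positive")
  if (length(object@extProp) != 2L)
    msg <- c(msg, "extProp must have length 2")
  for (a in c(object@alphaPeak, object@alphaMean, object@alphaVariance))
    if (!is.finite(a) || a <= 0 || a >= 1)
      msg <- c(msg, "alpha thresholds must lie in (0, 1)")
  if (object@roiHalfWidthProp < 0)
    msg <- c(msg, "roiHalfWidthProp must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a pipeline configuration
#'
#' @param flank,minCovDepth,sigma,kernelHalfWidth,zeroBand,extProp
#'   See [PipelineConfig-class].
#' @param roiHalfWidthProp,minDrop,alphaPeak,alphaMean,alphaVariance
#'   See [PipelineConfig-class].
#' @param copheneticThreshold,nLeveneComparisons,minNoiseSet See
#'   [PipelineConfig-class].
#' @param allowSingleReads,allowSoftClips,seed See [PipelineConfig-class].
#' @return A [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg
#' @export
pipelineConfig <- function(flank = 1000, minCovDepth = 15, sigma = 1.5,
                           kernelHalfWidth = 25L, zeroBand = 0.1,
                           extProp = c(-0.3, 1.0), roiHalfWidthProp = 0.5,
                           minDrop = 0.20, alphaPeak = 0.05, alphaMean = 0.05,
                           alphaVariance = 0.05, copheneticThreshold = 0.04,
                           nLeveneComparisons = 60L, minNoiseSet = 3L,
                           allowSingleReads = FALSE, allowSoftClips = FALSE,
                           seed = 1729L) {
  new("PipelineConfig", flank = flank, minCovDepth = minCovDepth,
      sigma = sigma, kernelHalfWidth = as.integer(kernelHalfWidth),
      zeroBand = zeroBand, extProp = as.numeric(extProp),
      roiHalfWidthProp = roiHalfWidthProp, minDrop = minDrop,
      alphaPeak = alphaPeak, alphaMean = alphaMean,
      alphaVariance = alphaVariance,
      copheneticThreshold = copheneticThreshold,
      nLeveneComparisons = as.integer(nLeveneComparisons),
      minNoiseSet = as.integer(minNoiseSet),
      allowSingleReads = allowSingleReads, allowSoftClips = allowSoftClips,
      seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  flank: %g nt | min riboswitch depth: %g\n",
              object@flank, object@minCovDepth))
  cat(sprintf("  kernel: sigma %g, %d elements | zero band (+/-%g)\n",
              object@sigma, 2L * object@kernelHalfWidth + 1L, object@zeroBand))
  cat(sprintf("  noise region extProp: (%g, %g) | ROI half width: %g x size\n",
              object@extProp[1], object@extProp[2], object@roiHalfWidthProp))
  cat(sprintf("  min drop: %g | alphas (peak/mean/var): %g/%g/%g\n",
              object@minDrop, object@alphaPeak, object@alphaMean,
              object@alphaVariance))
  cat(sprintf("  cophenetic threshold: %g | Levene comparisons: %d (seed %d)\n",
              object@copheneticThreshold, object@nLeveneComparisons,
              object@seed))
  cat(sprintf("  allowSingleReads: %s | allowSoftClips: %s\n",
              object@allowSingleReads, object@allowSoftClips))
})

#' Oriented riboswitch reference window
#'
#' A genomic neighborhood around one riboswitch locus, trimmed from its source
#' contig and always stored 5' to 3' with respect to the riboswitch: windows
#' for minus-strand loci hold the reverse complement of the contig slice. All
#' coordinates are 0-based half-open; riboswitch bounds are expressed in the
#' window frame.
#'
#' @slot locusId unique locus identifier.
#' @slot family riboswitch family (covariance-model name).
#' @slot sequence [Biostrings::DNAString] window sequence, riboswitch-oriented.
#' @slot contigId source contig identifier.
#' @slot windowStartOnContig 0-based start of the window on the source contig
#'   (always in contig coordinates, before any reverse complementing).
#' @slot riboswitchStart,riboswitchEnd 0-based half-open riboswitch bounds in
#'   window coordinates.
#' @slot strand source strand of the riboswitch, "+" or "-".
#' @slot wasReverseComplemented TRUE for windows derived from "-" strand loci.
#' @export
setClass("ReferenceWindow", representation(
  locusId = "character",
  family = "character",
  sequence = "DNAString",
  contigId = "character",
  windowStartOnContig = "integer",
  riboswitchStart = "integer",
  riboswitchEnd = "integer",
  strand = "character",
  wasReverseComplemented = "logical"
))

setValidity("ReferenceWindow", function(object) {
  msg <- character(0)
  if (object@riboswitchStart >= object@riboswitchEnd)
    msg <- c(msg, "riboswitchStart must be < riboswitchEnd")
  if (object@riboswitchStart < 0L ||
      object@riboswitchEnd > length(object@sequence))
    msg <- c(msg, "riboswitch bounds must lie within the window sequence")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReferenceWindow-class riboswitch length in nt.
#' @param x A `ReferenceWindow`.
#' @export
riboswitchSize <- function(x) x@riboswitchEnd - x@riboswitchStart

setMethod("show", "ReferenceWindow", function(object) {
  cat(sprintf(
    "ReferenceWindow %s (%s)\n  %d nt window from contig %s:%d (%s strand%s)\n  riboswitch [%d, %d) in window frame (%d nt)\n",
    object@locusId, object@family, length(object@sequence), object@contigId,
    object@windowStartOnContig, object@strand,
    if (object@wasReverseComplemented) ", reverse complemented" else "",
    object@riboswitchStart, object@riboswitchEnd, riboswitchSize(object)))
})

#' Per-locus, per-readset coverage pileups
#'
#' Five mutually exclusive coverage categories over the positions of one
#' reference window, plus the signed fragment-termini track that feeds the
#' edge-detection convolution. At every position the five categories sum to
#' the number of retained sequenced fragments covering that base.
#'
#' Categories: `readCoverage` (bases mapped by exactly one mate),
#' `clippedCoverage` (bases covered only by soft-clipped read regions),
#' `overlappedCoverage` (bases mapped by both mates), `inferredCoverage`
#' (unmapped bases between the two mates) and `terminiCoverage` (the
#' synthesis-origin base of each mate: the left-most mapped base of the
#' F-oriented read and the right-most mapped base of the R-oriented read).
#' `signedTermini` counts R-read termini as +1 and F-read termini as -1.
#'
#' @slot locusId,readsetId,conditionId identifiers.
#' @slot readCoverage,clippedCoverage,overlappedCoverage,inferredCoverage
#'   integer vectors over window positions.
#' @slot terminiCoverage integer vector over window positions.
#' @slot signedTermini integer vector, R termini +1 and F termini -1.
#' @slot roiCoverage,nonRoiCoverage integer fragment-interval coverage split
#'   by whether the pair's R-read origin lies inside the region of interest
#'   (used for locus plots; zero-length when no ROI was supplied).
#' @slot riboswitchStart,riboswitchEnd riboswitch bounds in window frame.
#' @slot nPairs named integer counts of pair dispositions.
#' @export
setClass("CoverageProfile", representation(
  locusId = "character",
  readsetId = "character",
  conditionId = "character",
  readCoverage = "integer",
  clippedCoverage = "integer",
  overlappedCoverage = "integer",
  inferredCoverage = "integer",
  terminiCoverage = "integer",
  signedTermini = "integer",
  roiCoverage = "integer",
  nonRoiCoverage = "integer",
  riboswitchStart = "integer",
  riboswitchEnd = "integer",
  nPairs = "integer"
))

setValidity("CoverageProfile", function(object) {
  msg <- character(0)
  n <- length(object@readCoverage)
  lens <- c(length(object@clippedCoverage), length(object@overlappedCoverage),
            length(object@inferredCoverage), length(object@terminiCoverage),
            length(object@signedTermini))
  if (any(lens != n))
    msg <- c(msg, "all coverage arrays must have the same length")
  if (any(object@readCoverage < 0L) || any(object@clippedCoverage < 0L) ||
      any(object@overlappedCoverage < 0L) ||
      any(object@inferredCoverage < 0L) || any(object@terminiCoverage < 0L))
    msg <- c(msg, "coverage counts must be non-negative")
  if (object@riboswitchStart >= object@riboswitchEnd)
    msg <- c(msg, "riboswitchStart must be < riboswitchEnd")
  if (length(msg)) msg else TRUE
})

#' Total coverage (read depth) track
#'
#' Elementwise sum of the five coverage categories; equals the number of
#' retained fragments (plus clipped extensions) covering each base.
#'
#' @param x A [CoverageProfile-class].
#' @return Integer vector over window positions.
#' @export
totalCoverage <- function(x) {
  x@readCoverage + x@clippedCoverage + x@overlappedCoverage +
    x@inferredCoverage + x@terminiCoverage
}

#' Signed fragment-termini track
#'
#' @param x A [CoverageProfile-class].
#' @return Integer vector: +1 per R-read origin, -1 per F-read origin.
#' @export
signedTermini <- function(x) x@signedTermini

#' Mean total coverage across the riboswitch
#'
#' @param x A [CoverageProfile-class].
#' @return Mean of [totalCoverage()] over riboswitch positions.
#' @export
meanRiboswitchCoverage <- function(x) {
  if (x@riboswitchEnd <= x@riboswitchStart)
    stop("zero-length riboswitch in profile ", x@locusId)
  tc <- totalCoverage(x)
  mean(tc[(x@riboswitchStart + 1L):x@riboswitchEnd])
}

setMethod("show", "CoverageProfile", function(object) {
  cat(sprintf(
    "CoverageProfile %s / readset %s (condition %s)\n  %d positions, riboswitch [%d, %d), mean riboswitch depth %.2f\n  pairs: %s\n",
    object@locusId, object@readsetId, object@conditionId,
    length(object@readCoverage), object@riboswitchStart,
    object@riboswitchEnd, meanRiboswitchCoverage(object),
    paste(names(object@nPairs), object@nPairs, sep = "=", collapse = " ")))
})

#' Bivariate noise model over peak shape
#'
#' Sample mean and covariance of (width, |amplitude|) for the noise set of
#' convolution peaks around one riboswitch, used to judge whether a candidate
#' termination peak is unusually sharp.
#'
#' @slot center numeric length-2 mean of (width, |amplitude|).
#' @slot covariance 2x2 covariance matrix (diagonal-regularized if singular).
#' @slot nPeaks number of peaks the model was fitted to.
#' @export
setClass("NoiseModel", representation(
  center = "numeric",
  covariance = "matrix",
  nPeaks = "integer"
))

setValidity("NoiseModel", function(object) {
  msg <- character(0)
  if (length(object@center) != 2L) msg <- c(msg, "center must have length 2")
  if (!all(dim(object@covariance) == c(2L, 2L)))
    msg <- c(msg, "covariance must be 2x2")
  if (abs(object@covariance[1, 2] - object@covariance[2, 1]) > 1e-8)
    msg <- c(msg, "covariance must be symmetric")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel over %d peaks\n  mean (width, |amp|): (%.3g, %.3g)\n  cov: [%.3g %.3g; %.3g %.3g]\n",
    object@nPeaks, object@center[1], object@center[2],
    object@covariance[1, 1], object@covariance[1, 2],
    object@covariance[2, 1], object@covariance[2, 2]))
})

#' Synthetic-data simulation specification
#'
#' Describes a ground-truthed single-locus experiment: a random reference
#' contig carrying one riboswitch, a transcription start site, and an
#' intrinsic terminator just past the riboswitch 3' end whose per-condition
#' termination efficiency is programmed. Transcript pools are fragmented with
#' truncated-lognormal fragment lengths and sequenced as paired-end reads.
#'
#' @slot seed base RNG seed; every emitted file is deterministic under it.
#' @slot windowLength contig/window length in nt.
#' @slot riboswitchStart,riboswitchEnd 0-based half-open riboswitch bounds.
#' @slot tssPosition transcription start site (0-based).
#' @slot terminatorPosition transcript 3' end under termination (0-based
#'   position of the last transcribed base + 1).
#' @slot terminatorJitterSd sd (nt) of Gaussian jitter on the termination site.
#' @slot conditions data.frame with columns `condition_id`, `n_readsets`,
#'   `n_transcripts`, `termination_efficiency`.
#' @slot fragMeanlog,fragSdlog lognormal fragment-length parameters.
#' @slot minFrag,maxFrag truncation bounds (nt) of the fragment lengths.
#' @slot readLength read length in nt.
#' @export
setClass("SimulationSpec", representation(
  seed = "integer",
  windowLength = "integer",
  riboswitchStart = "integer",
  riboswitchEnd = "integer",
  tssPosition = "integer",
  terminatorPosition = "integer",
  terminatorJitterSd = "numeric",
  conditions = "data.frame",
  fragMeanlog = "numeric",
  fragSdlog = "numeric",
  minFrag = "integer",
  maxFrag = "integer",
  readLength = "integer"
))

setValidity("SimulationSpec", function(object) {
  msg <- character(0)
  if (!(object@tssPosition < object@terminatorPosition &&
        object@terminatorPosition < object@windowLength))
    msg <- c(msg, "need tss < terminator < window length")
  if (object@riboswitchStart >= object@riboswitchEnd)
    msg <- c(msg, "riboswitchStart must be < riboswitchEnd")
  need <- c("condition_id", "n_readsets", "n_transcripts",
            "termination_efficiency")
  if (!all(need %in% names(object@conditions)))
    msg <- c(msg, paste("conditions needs columns:", paste(need, collapse = ", ")))
  else if (any(object@conditions$termination_efficiency < 0) ||
           any(object@conditions$termination_efficiency > 1))
    msg <- c(msg, "termination efficiencies must lie in [0, 1]")
  if (object@minFrag <= 0L || object@maxFrag < object@minFrag)
    msg <- c(msg, "need 0 < minFrag <= maxFrag")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation specification
#'
#' Defaults describe the package's standard synthetic experiment: a 3,000-nt
#' contig with a 150-nt riboswitch at [1200, 1350), TSS at 1,000, terminator
#' at 1,360 (10 nt past the riboswitch 3' end) with 1-nt jitter, two
#' conditions with termination efficiencies 0.9 ("A", OFF-leaning) and 0.1
#' ("B", ON-leaning), four readsets each, and 60 transcripts per readset
#' (roughly 60x riboswitch depth).
#'
#' @param seed,windowLength,riboswitchStart,riboswitchEnd,tssPosition
#'   See [SimulationSpec-class].
#' @param terminatorPosition,terminatorJitterSd,conditions See
#'   [SimulationSpec-class].
#' @param fragMeanlog,fragSdlog,minFrag,maxFrag,readLength See
#'   [SimulationSpec-class].
#' @return A [SimulationSpec-class] object.
#' @examples
#' spec <- simulationSpec(seed = 7)
#' spec
#' @export
simulationSpec <- function(seed = 1L, windowLength = 3000L,
                           riboswitchStart = 1200L, riboswitchEnd = 1350L,
                           tssPosition = 1000L, terminatorPosition = 1360L,
                           terminatorJitterSd = 1,
                           conditions = data.frame(
                             condition_id = c("A", "B"),
                             n_readsets = c(4L, 4L),
                             n_transcripts = c(60L, 60L),
                             termination_efficiency = c(0.9, 0.1),
                             stringsAsFactors = FALSE),
                           fragMeanlog = log(300), fragSdlog = 0.35,
                           minFrag = 100L, maxFrag = 1000L,
                           readLength = 150L) {
  new("SimulationSpec", seed = as.integer(seed),
      windowLength = as.integer(windowLength),
      riboswitchStart = as.integer(riboswitchStart),
      riboswitchEnd = as.integer(riboswitchEnd),
      tssPosition = as.integer(tssPosition),
      terminatorPosition = as.integer(terminatorPosition),
      terminatorJitterSd = terminatorJitterSd, conditions = conditions,
      fragMeanlog = fragMeanlog, fragSdlog = fragSdlog,
      minFrag = as.integer(minFrag), maxFrag = as.integer(maxFrag),
      readLength = as.integer(readLength))
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec (seed %d)\n  window %d nt, riboswitch [%d, %d), TSS %d, terminator %d (jitter sd %g)\n  fragments lognormal(meanlog %.3g, sdlog %.3g) in [%d, %d], reads %d nt\n",
    object@seed, object@windowLength, object@riboswitchStart,
    object@riboswitchEnd, object@tssPosition, object@terminatorPosition,
    object@terminatorJitterSd, object@fragMeanlog, object@fragSdlog,
    object@minFrag, object@maxFrag, object@readLength))
  print(object@conditions)
})
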