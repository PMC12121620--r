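# Per-locus, per-condition scoring of candidate termination peaks against a
# bivariate noise model of peak shape, plus the coverage-drop criterion.

#' Noise-set region around a riboswitch
#'
#' The region from which comparator peaks ("noise set") are drawn is defined
#' relative to riboswitch length: it spans from
#' `riboswitchStart - extProp[1] * size` to
#' `riboswitchEnd + extProp[2] * size`, clipped to the window. The default
#' `extProp = c(-0.3, 1.0)` excludes the first 30% of the riboswitch,
#' includes the remainder, and continues one full riboswitch length past the
#' 3' end.
#'
#' @param riboswitchStart,riboswitchEnd 0-based half-open riboswitch bounds
#'   in window coordinates.
#' @param extProp Length-2 numeric extension proportions.
#' @param windowLength Window length for clipping (optional).
#' @return Integer `c(from, to)`, 0-based half-open.
#' @examples
#' noiseRegion(1000, 1100)  # c(1030, 1200)
#' @export
noiseRegion <- function(riboswitchStart, riboswitchEnd,
                        extProp = c(-0.3, 1.0), windowLength = NULL) {
  size <- riboswitchEnd - riboswitchStart
  if (size <= 0) stop("riboswitch size must be positive")
  from <- as.integer(round(riboswitchStart - extProp[1] * size))
  to <- as.integer(round(riboswitchEnd + extProp[2] * size))
  from <- max(0L, from)
  if (!is.null(windowLength)) to <- min(as.integer(windowLength), to)
  if (from >= to)
    stop("noise region is empty for extProp (", extProp[1], ", ", extProp[2],
         ")")
  c(from, to)
}

#' Fit the bivariate noise model to a peak set
#'
#' Sample mean and covariance of `(width, |amplitude|)` over the noise set.
#' Singular covariance matrices (e.g. identical peaks) are regularized by
#' adding 1e-9 to the diagonal.
#'
#' @param widths,amplitudes Numeric vectors of the noise-set peak widths and
#'   (signed) amplitudes; absolute amplitudes are modeled.
#' @param minNoiseSet Minimum number of peaks required (default 3, the
#'   smallest set that supports a 2-D covariance).
#' @return A [NoiseModel-class], or `NULL` when fewer than `minNoiseSet`
#'   peaks are available.
#' @export
fitNoiseModel <- function(widths, amplitudes, minNoiseSet = 3L) {
  n <- length(widths)
  stopifnot(length(amplitudes) == n)
  if (n < minNoiseSet) return(NULL)
  m <- cbind(width = as.numeric(widths), amp = abs(as.numeric(amplitudes)))
  cv <- stats::cov(m)
  if (!is.finite(det(cv)) || det(cv) < .Machine$double.eps)
    cv <- cv + diag(1e-9, 2)
  new("NoiseModel", center = colMeans(m), covariance = cv,
      nPeaks = as.integer(n))
}

#' Pseudo p-value of a peak under the noise model
#'
#' The probability that a bivariate-normal draw from the noise model has
#' lower density than the observed `(width, |amplitude|)` point:
#' `exp(-d^2 / 2)` where `d^2` is the squared Mahalanobis distance. This is
#' the exact highest-density-region tail probability for a bivariate normal;
#' it equals 1 at the model mean and decreases monotonically with distance.
#' Peaks with `p < 0.05` are considered distinct from locus noise.
#'
#' @param width,amplitude Peak width (nt) and signed amplitude.
#' @param model A [NoiseModel-class].
#' @return Pseudo p-value in (0, 1].
#' @export
pseudoPValue <- function(width, amplitude, model) {
  d2 <- tryCatch(
    stats::mahalanobis(c(width, abs(amplitude)), model@center,
                       model@covariance),
    error = function(e) stop("singular noise covariance: ",
                             conditionMessage(e)))
  exp(-d2 / 2)
}

#' Fractional coverage change across a peak
#'
#' Difference in total coverage between the (exclusive) right bound and the
#' (inclusive) left bound of the peak, expressed as a fraction of the mean
#' total coverage across the riboswitch. Negative values are coverage drops;
#' a genuine termination event gives a drop comparable to the terminating
#' fraction of transcripts.
#'
#' @param leftBound,rightBound 0-based peak bounds (right exclusive).
#' @param profile A [CoverageProfile-class].
#' @return Fractional coverage change (negative for drops).
#' @export
coverageDrop <- function(leftBound, rightBound, profile) {
  denom <- meanRiboswitchCoverage(profile)
  if (denom == 0)
    stop("zero mean riboswitch coverage at locus ", profile@locusId)
  tc <- totalCoverage(profile)
  n <- length(tc)
  rb <- min(rightBound, n - 1L)  # clamp the exclusive bound at the last base
  (tc[rb + 1L] - tc[leftBound + 1L]) / denom
}

#' Score and call candidate termination peaks for one profile
#'
#' Computes, for every detected peak, the relative position and fractional
#' coverage change, and for positive peaks inside the noise-set region a
#' leave-one-out noise model, pseudo p-value and pass/fail call. A peak
#' passes when it is positive, lies in the region, the noise set has at
#' least `minNoiseSet` members, the pseudo p-value is below `alphaPeak`, and
#' the coverage drop is at least `minDrop` of mean riboswitch coverage. The
#' first failed criterion (in that order) is recorded as `fail_reason`.
#'
#' @param peaks Peak `data.frame` from [detectPeaks()].
#' @param profile The matching [CoverageProfile-class].
#' @param config A [PipelineConfig-class].
#' @return The peak frame augmented with `locus_id`, `readset_id`,
#'   `condition_id`, `relative_position`, `coverage_drop`, `noise_n`,
#'   `noise_mean_width`, `noise_mean_amp`, `pseudo_p`, `decision`
#'   (`"pass"`/`"fail"`) and `fail_reason`.
#' @export
callPeaks <- function(peaks, profile, config = pipelineConfig()) {
  rsStart <- profile@riboswitchStart
  rsEnd <- profile@riboswitchEnd
  size <- rsEnd - rsStart
  n <- nrow(peaks)
  out <- peaks
  out$locus_id <- rep(profile@locusId, n)
  out$readset_id <- rep(profile@readsetId, n)
  out$condition_id <- rep(profile@conditionId, n)
  out$relative_position <- (peaks$summit - rsEnd) / size
  out$coverage_drop <- vapply(seq_len(n), function(i) {
    coverageDrop(peaks$left_bound[i], peaks$right_bound[i], profile)
  }, 0)
  region <- noiseRegion(rsStart, rsEnd, config@extProp,
                        length(totalCoverage(profile)))
  inRegion <- peaks$summit >= region[1] & peaks$summit < region[2]
  out$in_noise_region <- inRegion
  out$noise_n <- NA_integer_
  out$noise_mean_width <- NA_real_
  out$noise_mean_amp <- NA_real_
  out$pseudo_p <- NA_real_
  out$decision <- rep("fail", n)
  out$fail_reason <- rep("none", n)
  for (i in seq_len(n)) {
    if (peaks$sign[i] != "+") { out$fail_reason[i] <- "wrong_sign"; next }
    if (!inRegion[i]) { out$fail_reason[i] <- "outside_region"; next }
    noise <- which(inRegion & seq_len(n) != i)
    model <- fitNoiseModel(peaks$width[noise], peaks$amplitude[noise],
                           config@minNoiseSet)
    if (is.null(model)) {
      out$noise_n[i] <- length(noise)
      out$fail_reason[i] <- "insufficient_noise_set"
      next
    }
    out$noise_n[i] <- model@nPeaks
    out$noise_mean_width[i] <- model@center[1]
    out$noise_mean_amp[i] <- model@center[2]
    p <- pseudoPValue(peaks$width[i], peaks$amplitude[i], model)
    out$pseudo_p[i] <- p
    if (p >= config@alphaPeak) { out$fail_reason[i] <- "not_significant"; next }
    if (out$coverage_drop[i] > -config@minDrop) {
      out$fail_reason[i] <- "insufficient_drop"
      next
    }
    out$decision[i] <- "pass"
  }
  out
}
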