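# Cross-condition comparison: clustering of peaks near the riboswitch 3' end
# and the mean (Mann-Whitney) and variance (resampled Levene) tests.

#' Region of interest around the riboswitch 3' end
#'
#' The search window for condition-dependent termination spans
#' `halfWidthProp * size` on each side of the riboswitch 3' end (relative
#' positions in `[-halfWidthProp, +halfWidthProp)`).
#'
#' @param riboswitchStart,riboswitchEnd 0-based half-open riboswitch bounds.
#' @param halfWidthProp Half width as a proportion of riboswitch size.
#' @return Integer `c(from, to)`, 0-based half-open window coordinates.
#' @examples
#' regionOfInterest(1000, 1100)  # c(1050, 1150)
#' @export
regionOfInterest <- function(riboswitchStart, riboswitchEnd,
                             halfWidthProp = 0.5) {
  size <- riboswitchEnd - riboswitchStart
  if (size <= 0) stop("riboswitch size must be positive")
  c(as.integer(round(riboswitchEnd - halfWidthProp * size)),
    as.integer(round(riboswitchEnd + halfWidthProp * size)))
}

#' Cluster peaks across conditions by relative position
#'
#' Agglomerative complete-linkage clustering of the peaks' relative
#' positions, cut where cophenetic distance is at most `threshold`, so the
#' maximum pairwise spread inside any cluster never exceeds the threshold.
#' Cluster ids are assigned in order of increasing centroid.
#'
#' @param peaks Peak `data.frame` with a `relative_position` column (all
#'   peaks at one locus, any condition, already restricted to the region of
#'   interest).
#' @param threshold Cophenetic distance threshold (default 0.04).
#' @return `peaks` with an integer `cluster` column added.
#' @export
clusterPeaks <- function(peaks, threshold = 0.04) {
  n <- nrow(peaks)
  if (n == 0L) {
    peaks$cluster <- integer(0)
    return(peaks)
  }
  if (n == 1L) {
    peaks$cluster <- 1L
    return(peaks)
  }
  # canonicalize on sorted positions so the partition is invariant to input
  # order (in 1-D, complete-linkage clusters are contiguous runs)
  ord <- order(peaks$relative_position)
  hc <- stats::hclust(stats::dist(peaks$relative_position[ord]),
                      method = "complete")
  raw <- stats::cutree(hc, h = threshold)[order(ord)]
  cent <- tapply(peaks$relative_position, raw, mean)
  peaks$cluster <- as.integer(rank(cent)[as.character(raw)])
  peaks
}

#' One-tailed Mann-Whitney test of a cluster's coverage-drop mean
#'
#' Tests whether the cluster's fractional coverage changes are
#' stochastically smaller (more negative) than those of all other peaks at
#' the locus. The exact null distribution is used for small tie-free
#' samples; larger or tied samples use the midrank normal approximation
#' with continuity correction.
#'
#' @param clusterValues,otherValues Numeric fractional coverage changes.
#' @return One-tailed p-value; `1` (with a warning) when there are no other
#'   peaks to compare against.
#' @export
testClusterMean <- function(clusterValues, otherValues) {
  if (length(otherValues) == 0L) {
    warning("no comparator peaks for the cluster mean test")
    return(1)
  }
  ties <- anyDuplicated(c(clusterValues, otherValues)) > 0L
  exact <- !ties && max(length(clusterValues), length(otherValues)) <= 8L
  suppressWarnings(
    stats::wilcox.test(clusterValues, otherValues, alternative = "less",
                       exact = exact, correct = TRUE)$p.value)
}

# Classical (mean-centered) two-group Levene test p-value.
.levene2 <- function(a, b) {
  vals <- c(a, b)
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  p <- tryCatch(
    suppressWarnings(car::leveneTest(vals, grp, center = mean)[1, "Pr(>F)"]),
    error = function(e) NA_real_)
  if (!is.null(p) && is.finite(p)) p else NA_real_
}

#' Resampled Levene test of a cluster's coverage-drop variance
#'
#' Cluster-size bias is handled by comparing the cluster of `n` peaks
#' against repeated size-`n` samples drawn without replacement from the
#' superset of all other peaks at the locus: each shuffled pass of the
#' superset yields `floor(N / n)` disjoint samples, and the superset is
#' reshuffled and resampled until at least `nComparisons` (default 60)
#' mean-centered Levene tests have been run. The median of the collected
#' p-values is returned.
#'
#' @param clusterValues Numeric coverage changes of the cluster (`n >= 2`).
#' @param supersetValues Coverage changes of all other peaks at the locus.
#' @param nComparisons Minimum number of Levene comparisons.
#' @param seed Integer seed for the resampling RNG (kept separate from the
#'   global RNG state).
#' @return Median Levene p-value, or `NA` for degenerate inputs (cluster
#'   smaller than 2, superset smaller than the cluster, or no defined
#'   Levene statistic).
#' @export
testClusterVariance <- function(clusterValues, supersetValues,
                                nComparisons = 60L, seed = 1729L) {
  n <- length(clusterValues)
  if (n < 2L || length(supersetValues) < n) return(NA_real_)
  ps <- numeric(0)
  withPrivateSeed(seed, {
    while (length(ps) < nComparisons) {
      perm <- sample(supersetValues)
      k <- length(perm) %/% n
      for (j in seq_len(k)) {
        ps <- c(ps, .levene2(clusterValues,
                             perm[((j - 1L) * n + 1L):(j * n)]))
        if (length(ps) >= nComparisons) break
      }
    }
  })
  ps <- ps[is.finite(ps)]
  if (length(ps) == 0L) return(NA_real_)
  stats::median(ps)
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
withPrivateSeed <- function(seed, code) {
  hasSeed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (hasSeed) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
  invisible(NULL)
}

#' Cluster-level tests and the per-locus verdict
#'
#' Applies the three-criterion rule to every cluster at a locus: a cluster
#' is significant when (i) it contains at least one passing termination
#' peak, (ii) its coverage-drop mean is significantly more negative than
#' that of all other peaks (one-tailed Mann-Whitney, `p < alphaMean`), and
#' (iii) its coverage-drop variance is significantly larger than
#' size-matched samples of other peaks (median resampled Levene,
#' `p < alphaVariance`). The locus verdict is `termination_evidence` when
#' any cluster is significant, `no_candidate_peaks` when the region of
#' interest holds no peaks, `low_coverage` when no readset passed the depth
#' filter, and `inconclusive` otherwise.
#'
#' @param clusteredPeaks Output of [clusterPeaks()] joined with the
#'   [callPeaks()] columns (`decision`, `coverage_drop`, `condition_id`).
#' @param locusId,family Locus identifiers for the verdict row.
#' @param conditionStates Named logical: for each analyzed condition, whether
#'   any passing termination peak was observed anywhere at the locus.
#' @param anyDepthPass Whether any readset passed the depth filter.
#' @param config A [PipelineConfig-class].
#' @return List with `clusters` (one row per cluster: centroid, member
#'   count, conditions, test p-values, decision) and `verdict` (one-row
#'   locus `data.frame`).
#' @export
callLocus <- function(clusteredPeaks, locusId, family = "unknown",
                      conditionStates = logical(0), anyDepthPass = TRUE,
                      config = pipelineConfig()) {
  emptyClusters <- data.frame(
    locus_id = character(0), cluster = integer(0), centroid = numeric(0),
    n_members = integer(0), n_conditions = integer(0),
    conditions = character(0), has_passing_peak = logical(0),
    mean_test_p = numeric(0), variance_test_p = numeric(0),
    decision = character(0), stringsAsFactors = FALSE)
  verdict <- if (!anyDepthPass) "low_coverage"
             else if (nrow(clusteredPeaks) == 0L) "no_candidate_peaks"
             else "inconclusive"
  clusters <- emptyClusters
  if (nrow(clusteredPeaks) > 0L) {
    rows <- lapply(sort(unique(clusteredPeaks$cluster)), function(cl) {
      inCl <- clusteredPeaks$cluster == cl
      vals <- clusteredPeaks$coverage_drop[inCl]
      others <- clusteredPeaks$coverage_drop[!inCl]
      hasPass <- any(clusteredPeaks$decision[inCl] == "pass")
      meanP <- if (length(others)) testClusterMean(vals, others) else NA_real_
      varP <- testClusterVariance(vals, others,
                                  config@nLeveneComparisons, config@seed)
      sig <- isTRUE(hasPass) && isTRUE(meanP < config@alphaMean) &&
        isTRUE(varP < config@alphaVariance)
      data.frame(
        locus_id = locusId, cluster = cl,
        centroid = mean(clusteredPeaks$relative_position[inCl]),
        n_members = sum(inCl),
        n_conditions = length(unique(clusteredPeaks$condition_id[inCl])),
        conditions = paste(sort(unique(clusteredPeaks$condition_id[inCl])),
                           collapse = ";"),
        has_passing_peak = hasPass, mean_test_p = meanP,
        variance_test_p = varP,
        decision = if (sig) "significant" else "not_significant",
        stringsAsFactors = FALSE)
    })
    clusters <- do.call(rbind, rows)
    if (any(clusters$decision == "significant"))
      verdict <- "termination_evidence"
  }
  verdictRow <- data.frame(
    locus_id = locusId, family = family,
    n_conditions_analyzed = length(conditionStates),
    n_clusters = nrow(clusters),
    n_significant_clusters = sum(clusters$decision == "significant"),
    verdict = verdict,
    conditions_with_termination = paste(
      names(conditionStates)[conditionStates], collapse = ";"),
    stringsAsFactors = FALSE)
  list(clusters = clusters, verdict = verdictRow)
}
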