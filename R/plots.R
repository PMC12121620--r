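# Locus and peak-summary plots (base graphics).

#' Locus plot: stacked coverage panels plus the convolution track
#'
#' Four panels over window position: fragment coverage for pairs whose
#' R-read origin lies inside the region of interest; the same for pairs
#' starting outside it; their union (total fragment coverage); and the
#' Gaussian-convolution amplitude with detected peak bounds. Each panel is
#' scaled to its own maximum. The riboswitch span is shaded.
#'
#' @param profile A [CoverageProfile-class] built with an `roi`.
#' @param conv Convolution track for the profile.
#' @param peakCalls Optional [callPeaks()] frame for peak annotations.
#' @return Invisibly, `NULL`.
#' @export
plotLocusProfile <- function(profile, conv, peakCalls = NULL) {
  n <- length(totalCoverage(profile))
  x <- seq_len(n) - 1L
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.2, 4, 1.4, 1))
  on.exit(graphics::par(op))
  shade <- function() graphics::rect(profile@riboswitchStart, -1e9,
                                     profile@riboswitchEnd, 1e9,
                                     col = "#00000012", border = NA)
  panels <- list(
    list(y = profile@roiCoverage, main = "pairs with R-read origin in ROI"),
    list(y = profile@nonRoiCoverage,
         main = "pairs with R-read origin outside ROI"),
    list(y = totalCoverage(profile), main = "total fragment coverage"))
  for (p in panels) {
    y <- if (length(p$y)) p$y else integer(n)
    graphics::plot(x, y, type = "h", col = "grey40", xlab = "",
                   ylab = "coverage", main = sprintf(
                     "%s | %s | %s", profile@locusId, profile@readsetId,
                     p$main), cex.main = 0.9)
    shade()
  }
  graphics::plot(x, conv, type = "l", col = "steelblue", xlab = "position",
                 ylab = "amplitude", main = "signed-termini convolution",
                 cex.main = 0.9)
  graphics::abline(h = c(-0.1, 0.1), lty = 3, col = "grey60")
  shade()
  if (!is.null(peakCalls) && nrow(peakCalls)) {
    pass <- peakCalls$decision == "pass"
    graphics::points(peakCalls$summit, peakCalls$amplitude,
                     pch = ifelse(pass, 19, 1),
                     col = ifelse(pass, "firebrick", "grey50"))
  }
  invisible(NULL)
}

#' Peak summary plot: coverage change vs relative position
#'
#' Each point is one convolution peak in the region of interest, at its
#' position relative to the riboswitch 3' end (fractions of riboswitch
#' size), with its fractional coverage change on the y axis. Lines connect
#' peaks from the same readset; ellipses outline clusters (solid when the
#' cluster holds a passing termination peak, dashed otherwise) and
#' asterisks mark clusters passing all three significance criteria.
#'
#' @param clusteredPeaks Output of [clusterPeaks()] with call columns.
#' @param clusterStats Cluster frame from [callLocus()].
#' @param window The locus [ReferenceWindow-class] (for the title).
#' @return Invisibly, `NULL`.
#' @export
plotPeakSummary <- function(clusteredPeaks, clusterStats, window = NULL) {
  main <- if (is.null(window)) "peak summary" else
    sprintf("%s (%s)", window@locusId, window@family)
  if (is.null(clusteredPeaks) || nrow(clusteredPeaks) == 0L) {
    graphics::plot(0, 0, type = "n", xlim = c(-0.6, 0.6), ylim = c(-1, 1),
                   xlab = "position relative to riboswitch 3' end",
                   ylab = "fractional coverage change", main = main)
    graphics::text(0, 0, "no peaks in region of interest", col = "grey50")
    return(invisible(NULL))
  }
  xr <- range(clusteredPeaks$relative_position)
  yr <- range(clusteredPeaks$coverage_drop)
  pad <- function(r) r + c(-1, 1) * max(0.05, diff(r) * 0.15)
  conds <- sort(unique(clusteredPeaks$condition_id))
  cols <- stats::setNames(grDevices::hcl.colors(max(3L, length(conds)),
                                                "Dark 3")[seq_along(conds)],
                          conds)
  graphics::plot(NA, xlim = pad(xr), ylim = pad(yr),
                 xlab = "position relative to riboswitch 3' end",
                 ylab = "fractional coverage change", main = main)
  graphics::abline(h = 0, col = "grey80")
  graphics::abline(v = 0, col = "grey80", lty = 2)
  for (rid in unique(clusteredPeaks$readset_id)) {
    sub <- clusteredPeaks[clusteredPeaks$readset_id == rid, ]
    sub <- sub[order(sub$relative_position), ]
    graphics::lines(sub$relative_position, sub$coverage_drop,
                    col = cols[sub$condition_id[1]], lwd = 0.8)
    graphics::points(sub$relative_position, sub$coverage_drop,
                     col = cols[sub$condition_id[1]],
                     pch = ifelse(sub$decision == "pass", 19, 1))
  }
  if (!is.null(clusterStats) && nrow(clusterStats)) {
    for (i in seq_len(nrow(clusterStats))) {
      cl <- clusterStats$cluster[i]
      sub <- clusteredPeaks[clusteredPeaks$cluster == cl, ]
      cx <- mean(range(sub$relative_position))
      cy <- mean(range(sub$coverage_drop))
      rx <- max(0.02, diff(range(sub$relative_position)) / 2 * 1.4)
      ry <- max(0.04, diff(range(sub$coverage_drop)) / 2 * 1.4)
      th <- seq(0, 2 * pi, length.out = 120)
      graphics::lines(cx + rx * cos(th), cy + ry * sin(th),
                      lty = if (clusterStats$has_passing_peak[i]) 1 else 2,
                      col = "grey30")
      if (clusterStats$decision[i] == "significant")
        graphics::text(cx, cy + ry * 1.25, "*", cex = 2, col = "firebrick")
    }
  }
  graphics::legend("bottomleft", legend = conds, col = cols[conds], pch = 19,
                   bty = "n", cex = 0.8)
  invisible(NULL)
}
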