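test_that("the noise-set region scales with riboswitch size", {
  expect_equal(noiseRegion(1000, 1100, c(-0.3, 1.0)), c(1030L, 1200L))
  expect_equal(noiseRegion(1000, 1100, c(0, 0)), c(1000L, 1100L))
  expect_error(noiseRegion(1000, 1100, c(-1.0, 0)), "empty")
  # clipping at window bounds
  expect_equal(noiseRegion(50, 150, c(1.0, 1.0), windowLength = 200),
               c(0L, 200L))
})

test_that("the noise model is the sample mean/covariance of (width, |amp|)", {
  m <- fitNoiseModel(c(4, 5, 6), c(0.2, 0.25, 0.3))
  expect_s4_class(m, "NoiseModel")
  expect_equal(unname(m@center), c(5, 0.25))
  expect_equal(m@nPeaks, 3L)

  # negative amplitudes enter as absolute values
  m2 <- fitNoiseModel(c(4, 5, 6), c(-0.2, 0.25, -0.3))
  expect_equal(unname(m2@center), c(5, 0.25))

  # identical peaks give a singular covariance, regularized not fatal
  m3 <- fitNoiseModel(c(5, 5, 5), c(0.2, 0.2, 0.2))
  expect_true(det(m3@covariance) > 0)
  expect_equal(pseudoPValue(5, 0.2, m3), 1)

  expect_null(fitNoiseModel(c(4, 5), c(0.2, 0.25)))
})

test_that("a 200-draw MVN sample recovers its parameters", {
  set.seed(101)
  n <- 200
  w <- stats::rnorm(n, 10, 2)
  a <- 0.3 + 0.05 * (w - 10) + stats::rnorm(n, 0, 0.04)
  m <- fitNoiseModel(w, a)
  expect_equal(unname(m@center[1]), 10, tolerance = 0.05)
  expect_equal(unname(m@center[2]), 0.3, tolerance = 0.05)
  expect_equal(m@covariance[1, 1], 4, tolerance = 0.25)
})

test_that("the pseudo p-value is the exact bivariate-normal tail", {
  m <- new("NoiseModel", center = c(5, 0.25),
           covariance = diag(c(1, 0.01)), nPeaks = 10L)
  expect_equal(pseudoPValue(5, 0.25, m), 1)
  # boundary of significance at squared Mahalanobis distance 5.9915
  d <- sqrt(5.9915)
  expect_equal(pseudoPValue(5 + d, 0.25, m), 0.05, tolerance = 1e-4)
  expect_lt(pseudoPValue(5 + sqrt(50), 0.25, m), 1e-10)

  # monotone decreasing in distance
  ps <- vapply(seq(0, 4, by = 0.5), function(dx)
    pseudoPValue(5 + dx, 0.25, m), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("pseudo p matches Monte-Carlo density ranking", {
  m <- new("NoiseModel", center = c(6, 0.3),
           covariance = matrix(c(2, 0.1, 0.1, 0.02), 2), nPeaks = 50L)
  set.seed(77)
  ch <- chol(m@covariance)
  draws <- sweep(matrix(stats::rnorm(2e5), ncol = 2) %*% ch, 2, m@center,
                 "+")
  d2 <- stats::mahalanobis(draws, m@center, m@covariance)
  for (point in list(c(7, 0.35), c(9, 0.6), c(6.5, 0.31))) {
    mcP <- mean(d2 > stats::mahalanobis(point, m@center, m@covariance))
    expect_lt(abs(pseudoPValue(point[1], point[2], m) - mcP), 0.005)
  }
})

makeFlatProfile <- function(levels, rsStart = 30L, rsEnd = 60L) {
  n <- length(levels)
  new("CoverageProfile", locusId = "l", readsetId = "r", conditionId = "c",
      readCoverage = as.integer(levels), clippedCoverage = integer(n),
      overlappedCoverage = integer(n), inferredCoverage = integer(n),
      terminiCoverage = integer(n), signedTermini = integer(n),
      roiCoverage = integer(0), nonRoiCoverage = integer(0),
      riboswitchStart = rsStart, riboswitchEnd = rsEnd,
      nPairs = c(EQ = 0L))
}

test_that("fractional coverage change uses the exclusive right bound", {
  depth <- c(rep(100L, 80), rep(70L, 20))
  prof <- makeFlatProfile(depth, rsStart = 0L, rsEnd = 60L)
  expect_equal(coverageDrop(70L, 85L, prof), -0.30)
  flat <- makeFlatProfile(rep(50L, 100), rsStart = 0L, rsEnd = 60L)
  expect_equal(coverageDrop(10L, 30L, flat), 0)
  zero <- makeFlatProfile(rep(0L, 100), rsStart = 0L, rsEnd = 60L)
  expect_error(coverageDrop(10L, 30L, zero), "zero mean")
})

test_that("coverage drop tracks programmed termination efficiency", {
  spec <- simulationSpec(seed = 21, conditions = data.frame(
    condition_id = "A", n_readsets = 1L, n_transcripts = 400L,
    termination_efficiency = 0.4))
  dir <- tempfile()
  sim <- simulateDataset(spec, dir)
  prof <- buildCoverageProfile(sim$manifest$sam[1], sim$window,
                               readsetId = "A_rep1", conditionId = "A")
  conv <- convolveSignedTermini(signedTermini(prof))
  peaks <- detectPeaks(conv)
  calls <- callPeaks(peaks, prof)
  term <- calls[calls$sign == "+" & calls$in_noise_region, ]
  term <- term[which.max(abs(term$amplitude)), ]
  # drop across the terminator peak ~ -0.4 (binomial error at n=400)
  expect_lt(abs(term$coverage_drop - (-0.4)), 0.08)
})

test_that("peak calls fail for the first unmet criterion in order", {
  set.seed(55)
  n <- 400L
  signed <- integer(n)
  # strong terminator pileup just past the riboswitch 3' end (pos 260)
  signed[261] <- 30L
  # matched F starts at the TSS
  signed[101] <- -30L
  # small noise peaks inside the region
  noisePos <- c(240, 275, 290, 310)
  signed[noisePos + 1L] <- 2L
  prof <- makeFlatProfile(rep(40L, n), rsStart = 150L, rsEnd = 250L)
  prof@readCoverage[262:n] <- 10L
  conv <- convolveSignedTermini(signed)
  peaks <- detectPeaks(conv)
  calls <- callPeaks(peaks, prof)
  expect_true(all(calls$fail_reason[calls$sign == "-"] == "wrong_sign"))
  big <- calls[calls$summit == 260, ]
  expect_equal(big$decision, "pass")
  expect_lt(big$pseudo_p, 0.05)
  expect_lt(big$coverage_drop, -0.20)

  # outside the noise region
  outside <- callPeaks(data.frame(summit = 100L, left_bound = 95L,
                                  right_bound = 105L, amplitude = 5,
                                  width = 10L, sign = "+"), prof)
  expect_equal(outside$fail_reason, "outside_region")

  # too few comparators
  few <- data.frame(summit = c(260L, 270L), left_bound = c(255L, 268L),
                    right_bound = c(265L, 273L), amplitude = c(5, 1),
                    width = c(10L, 5L), sign = "+")
  fewCalls <- callPeaks(few, prof)
  expect_true(all(fewCalls$fail_reason == "insufficient_noise_set"))
})

test_that("null peaks drawn from one MVN are flagged at the alpha rate", {
  set.seed(911)
  n <- 3000
  w <- stats::rnorm(n, 8, 1.5)
  a <- stats::rnorm(n, 0.3, 0.05)
  model <- fitNoiseModel(w, a)
  ps <- exp(-stats::mahalanobis(cbind(w, abs(a)), model@center,
                                model@covariance) / 2)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.012)  # 3 sigma binomial at n=3000
})
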