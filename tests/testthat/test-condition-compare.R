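test_that("the region of interest brackets the riboswitch 3' end", {
  expect_equal(regionOfInterest(1000, 1100), c(1050L, 1150L))
  roi0 <- regionOfInterest(1000, 1100, 0)
  expect_equal(roi0[1], roi0[2])  # empty interval
  # a summit at 1110 sits 10% of the riboswitch length downstream
  expect_equal((1110 - 1100) / 100, 0.10)
})

peakFrame <- function(relpos, drop = rep(0, length(relpos)),
                      decision = rep("fail", length(relpos)),
                      condition = rep("A", length(relpos))) {
  data.frame(relative_position = relpos, coverage_drop = drop,
             decision = decision, condition_id = condition,
             readset_id = condition, summit = seq_along(relpos),
             stringsAsFactors = FALSE)
}

test_that("complete-linkage clustering cuts at the cophenetic threshold", {
  cl <- clusterPeaks(peakFrame(c(0.00, 0.01, 0.30)), 0.04)
  expect_equal(cl$cluster, c(1L, 1L, 2L))

  single <- clusterPeaks(peakFrame(0.1), 0.04)
  expect_equal(single$cluster, 1L)

  # 0.00-0.06 spans more than the threshold under complete linkage
  cl3 <- clusterPeaks(peakFrame(c(0.00, 0.03, 0.06)), 0.04)
  expect_equal(length(unique(cl3$cluster)), 2L)
  expect_equal(cl3$cluster[1], cl3$cluster[2])

  empty <- clusterPeaks(peakFrame(numeric(0)), 0.04)
  expect_equal(nrow(empty), 0L)
})

test_that("clustering matches the brute-force oracle and ignores order", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(2:12, 1L)
    x <- stats::runif(n, -0.5, 0.5)
    got <- clusterPeaks(peakFrame(x), 0.04)$cluster
    want <- completeLinkageOracle(x, 0.04)
    # same partition (labels may differ)
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
    # max spread within any cluster respects the threshold
    for (k in unique(got)) expect_lte(diff(range(x[got == k])), 0.04)
    # permutation invariance
    perm <- sample(n)
    got2 <- clusterPeaks(peakFrame(x[perm]), 0.04)$cluster
    expect_equal(outer(got2, got2, "=="),
                 outer(got[perm], got[perm], "=="))
  }
})

test_that("the cluster mean test matches exact U enumeration", {
  p <- testClusterMean(c(-0.9, -0.8, -0.85), c(0.0, 0.01, -0.02, 0.03))
  expect_equal(p, 1 / 35)
  expect_lt(p, 0.05)

  # agreement with enumeration for random tie-free samples, n1+n2 <= 10
  set.seed(47)
  for (i in 1:40) {
    n1 <- sample(2:5, 1L); n2 <- sample(2:5, 1L)
    x <- round(stats::rnorm(n1), 6); y <- round(stats::rnorm(n2), 6)
    expect_equal(testClusterMean(x, y), mwExactOracle(x, y),
                 tolerance = 1e-12)
  }

  # wrong-direction alternative
  expect_gt(testClusterMean(c(0.5, 0.6, 0.7), c(-0.1, 0.0, 0.1)), 0.9)
  expect_warning(pNone <- testClusterMean(c(-1, -2), numeric(0)),
                 "no comparator")
  expect_equal(pNone, 1)
})

test_that("same-distribution clusters give uniform-ish mean-test p", {
  set.seed(53)
  ps <- replicate(200, {
    vals <- stats::rnorm(12)
    testClusterMean(vals[1:4], vals[5:12])
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("the resampled Levene test detects variance inflation", {
  set.seed(59)
  superset <- stats::rnorm(20, 0.01, 0.005)
  pWide <- testClusterVariance(c(-0.9, 0.0), superset, seed = 11)
  expect_lt(pWide, 0.05)

  # cluster drawn from the superset distribution is usually unremarkable
  pNull <- replicate(30, {
    cl <- stats::rnorm(4, 0.01, 0.005)
    testClusterVariance(cl, stats::rnorm(20, 0.01, 0.005),
                        seed = sample.int(1e6, 1))
  })
  expect_gt(mean(pNull > 0.05), 0.7)

  # degenerate inputs
  expect_true(is.na(testClusterVariance(c(-0.9), superset)))
  expect_true(is.na(testClusterVariance(c(-0.9, 0), stats::rnorm(1))))
})

test_that("nComparisons = 1 reduces to a single Levene p-value", {
  set.seed(61)
  cl <- c(-0.5, 0.2, 0.1)
  superset <- stats::rnorm(3, 0, 0.01)
  p1 <- testClusterVariance(cl, superset, nComparisons = 1L, seed = 99)
  # with |superset| == n there is only one possible sample
  grp <- factor(rep(c("a", "b"), each = 3))
  want <- car::leveneTest(c(cl, superset), grp, center = mean)[1, "Pr(>F)"]
  expect_equal(p1, want)
})

test_that("the Levene resampling is reproducible and seed-sensitive", {
  set.seed(67)
  cl <- stats::rnorm(4); superset <- stats::rnorm(30)
  a <- testClusterVariance(cl, superset, seed = 1)
  b <- testClusterVariance(cl, superset, seed = 1)
  expect_identical(a, b)
  # the private RNG leaves the global stream untouched
  set.seed(73); x1 <- stats::runif(1)
  set.seed(73); invisible(testClusterVariance(cl, superset, seed = 2))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("the three-criterion rule drives cluster and locus decisions", {
  cfg <- pipelineConfig()
  # a tight very-negative cluster from two conditions vs scattered others
  peaks <- rbind(
    peakFrame(c(-0.01, 0.00, 0.005, 0.01),
              drop = c(-0.9, -0.85, -0.5, -0.1),
              decision = c("pass", "pass", "fail", "fail"),
              condition = c("A", "A", "B", "B")),
    peakFrame(seq(0.2, 0.45, length.out = 8),
              drop = stats::rnorm(8, 0, 0.01),
              condition = rep(c("A", "B"), 4)))
  clustered <- clusterPeaks(peaks, cfg@copheneticThreshold)
  call <- callLocus(clustered, "locusX", "TPP",
                    conditionStates = c(A = TRUE, B = FALSE),
                    anyDepthPass = TRUE, config = cfg)
  sig <- call$clusters[call$clusters$decision == "significant", ]
  expect_equal(nrow(sig), 1L)
  expect_true(sig$has_passing_peak)
  expect_lt(sig$mean_test_p, 0.05)
  expect_lt(sig$variance_test_p, 0.05)
  expect_equal(call$verdict$verdict, "termination_evidence")
  expect_equal(call$verdict$conditions_with_termination, "A")

  # same clusters but no passing peak anywhere -> inconclusive
  peaks2 <- peaks
  peaks2$decision <- "fail"
  call2 <- callLocus(clusterPeaks(peaks2, 0.04), "locusX", "TPP",
                     conditionStates = c(A = FALSE, B = FALSE),
                     anyDepthPass = TRUE, config = cfg)
  expect_equal(call2$verdict$verdict, "inconclusive")
  expect_true(all(call2$clusters$decision == "not_significant"))

  # no peaks at all / no depth
  expect_equal(callLocus(peakFrame(numeric(0)), "l", "f",
                         anyDepthPass = TRUE)$verdict$verdict,
               "no_candidate_peaks")
  expect_equal(callLocus(peakFrame(numeric(0)), "l", "f",
                         anyDepthPass = FALSE)$verdict$verdict,
               "low_coverage")
})
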