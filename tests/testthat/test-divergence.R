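test_that("dS filtering uses inclusive bounds and drops saturated pairs", {
  pairs <- data.frame(gene = letters[1:6],
                      dS = c(2.5, 0.0005, 0.24, 0.001, 2, NA),
                      saturated = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  kept <- suppressMessages(filterPairs(pairs))
  expect_equal(kept$gene, c("c", "d", "e"))
})

test_that("the rate/time chain reproduces the printed arithmetic", {
  expect_equal(signif(autosomalRate(0.94, 167e6), 2), 2.8e-9)
  expect_equal(autosomalRate(2.0, 1e9), 1e-9)
  expect_equal(autosomalRate(0.94, 167e6), 0.94 / 334e6, tolerance = 1e-15)
  expect_equal(sexLinkedRate(RateModel()), 3.8e-9, tolerance = 1e-15)
  expect_equal(sexLinkedRate(RateModel(muA = 2.4e-9, rounding = NA)),
               3.24e-9, tolerance = 1e-15)
  expect_equal(sexLinkedRate(RateModel(zRatio = 1, femaleFraction = 1,
                                       rounding = NA)),
               2 * 2.8e-9, tolerance = 1e-15)
})

test_that("dS-to-time conversion is linear and matches the reported dates", {
  expect_equal(round(dsToTime(0.33, 3.8e-9, unit = "Ma")), 87)
  expect_equal(round(dsToTime(0.33, 3.24e-9, unit = "Ma")), 102)
  expect_equal(dsToTime(0, 3.8e-9), 0)
  expect_equal(dsToTime(0.66, 3.8e-9), 2 * dsToTime(0.33, 3.8e-9))
})

test_that("breakpoint stratum assignment bins genes by Z position", {
  pairs <- data.frame(gene = paste0("g", 1:10),
                      z_position = c(1:5 * 1e5, 6:10 * 1e6),
                      dS = c(rep(0.33, 5), rep(0.16, 5)))
  asg <- assignStrata(pairs, breakpoints = 3e6)
  expect_equal(as.character(asg$stratum_assigned),
               rep(c("stratum1", "stratum2"), each = 5))
  expect_equal(unname(attr(asg, "stratum_means")), c(0.33, 0.16))
  expect_equal(attr(asg, "age_rank"), c("stratum1", "stratum2"))
  merged <- assignStrata(pairs, breakpoints = 3e6,
                         merge = list(older = 1, recent = 2))
  expect_equal(merged$superstratum, rep(c("older", "recent"), each = 5))
})

test_that("k-means stratum assignment recovers non-overlapping position clusters", {
  old <- simulateGametologPairs(15, 120, 0.33, 0.4, seed = 21,
                                zPositionRange = c(0, 4e7),
                                stratumLabel = "older")
  rec <- simulateGametologPairs(15, 120, 0.16, 0.4, seed = 22,
                                zPositionRange = c(6e7, 9e7),
                                stratumLabel = "recent")
  est <- rbind(ng86(old), ng86(rec))
  asg <- assignStrata(est, kClusters = 2, seed = 1)
  expect_equal(as.character(asg$stratum_assigned),
               rep(c("stratum1", "stratum2"), each = 15))
  expect_error(assignStrata(est, kClusters = 31), "more clusters")
  expect_error(assignStrata(est), "exactly one")
})

test_that("stratum summary reports means, U statistics and Levene's test", {
  pairs <- data.frame(dS = c(1, 2, 3, 4, 5, 6),
                      omega = rep(0.3, 6),
                      stratum_assigned = rep(c("a", "b"), each = 3))
  res <- stratumSummary(pairs)
  expect_equal(res$summary$mean_dS, c(2, 5))
  # complete separation: first group's U is 0
  expect_equal(res$pairwise$U, 0)
  same <- data.frame(dS = rep(c(1, 2, 3, 4), 2),
                     stratum_assigned = rep(c("a", "b"), each = 4))
  resSame <- stratumSummary(same)
  expect_gt(resSame$pairwise$p_value, 0.95)
  expect_error(stratumSummary(pairs[1:3, ]), "2 strata")
})

test_that("simulated strata separate significantly with the expected means", {
  old <- simulateGametologPairs(25, 300, 0.33, 0.4, seed = 31,
                                zPositionRange = c(0, 5e7))
  rec <- simulateGametologPairs(25, 300, 0.16, 0.4, seed = 32,
                                zPositionRange = c(6e7, 9e7))
  est <- rbind(ng86(old), ng86(rec))
  asg <- assignStrata(est, breakpoints = 5.5e7)
  res <- stratumSummary(asg)
  expect_lt(abs(res$summary$mean_dS[1] - 0.33), 0.03)
  expect_lt(abs(res$summary$mean_dS[2] - 0.16), 0.03)
  expect_lt(res$pairwise$p_value, 0.01)
})

test_that("GC3 counts third positions with ambiguity exclusion", {
  expect_equal(gc3("ATGGCC"), 1)
  expect_equal(gc3("ATTAAA"), 0)
  expect_equal(gc3(c("ATGGCC", "ATTAAA")), c(1, 0))
  expect_equal(gc3("ATGGCNATT"), 0.5)  # ambiguous third base dropped
  expect_error(gc3("ATGG"), "multiple")
  expect_error(gc3(""), "empty")
})

test_that("GC3 comparison handles ties and detects W-biased GC", {
  eq <- gc3Compare(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$fraction_w_higher, 0)
  res <- gc3Compare(c(0.4, 0.45, 0.5, 0.42), c(0.6, 0.62, 0.58, 0.61))
  expect_equal(res$fraction_w_higher, 1)
  expect_lt(res$p_value, 0.01)
})
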