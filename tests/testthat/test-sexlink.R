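make_profile <- function(f, m, truth = NULL) {
  df <- data.frame(chrom = paste0("s", seq_along(f)),
                   start = 0, end = 10000,
                   female_depth = f, male_depth = m)
  if (!is.null(truth)) df$truth_class <- truth
  DepthProfile(df)
}

test_that("autosomal median uses the sample-median convention per sex", {
  p <- make_profile(c(10, 20, 30), c(30, 20, 10),
                    truth = rep("autosome", 3))
  expect_equal(unname(autosomalMedian(p)), c(20, 20))
  p4 <- make_profile(c(10, 20, 30, 40), c(40, 30, 20, 10),
                     truth = rep("autosome", 4))
  expect_equal(unname(autosomalMedian(p4)), c(25, 25))
  noLab <- make_profile(1, 1)
  expect_error(autosomalMedian(noLab), "labels")
  wrongLab <- make_profile(1, 1, truth = "W")
  expect_error(autosomalMedian(wrongLab), "autosome")
})

test_that("autosomal median recovers the simulated mean depth", {
  layout <- GenomeLayout(data.frame(name = "chr1", class = "autosome",
                                    length = 5e7), windowSize = 1e4)
  prof <- simulateDepthProfiles(layout, meanDepth = 30, dispersion = 10,
                                seed = 2)
  med <- autosomalMedian(prof)
  # depth is integer-valued and NB-skewed, so the median sits within a
  # couple of counts of the mean rather than on it exactly
  expect_lt(abs(med[["female"]] - 30), 2)
  expect_lt(abs(med[["male"]] - 30), 2)
})

test_that("log2FM matches the analytic sex-linkage expectations", {
  expect_equal(log2FM(1, 1), 0)
  expect_equal(log2FM(0.5, 1), -1)
  expect_equal(log2FM(0.5, 0.125), 2)
  expect_true(is.na(log2FM(0, 0, pseudocount = 0)))
  expect_equal(log2FM(0, 0, pseudocount = 0.05), 0)
  expect_error(log2FM(-1, 1), ">= 0")
})

test_that("log2FM is antisymmetric with zero pseudocount", {
  set.seed(3)
  a <- runif(50, 0.01, 3)
  b <- runif(50, 0.01, 3)
  expect_equal(log2FM(a, b), -log2FM(b, a), tolerance = 1e-12)
})

test_that("log2FM classification respects the strict >= threshold and bands", {
  p <- make_profile(rep(30, 6), rep(30, 6), truth = rep("autosome", 6))
  win <- depthWindows(p)
  S4Vectors::mcols(win)$female_norm <- rep(1, 6)
  S4Vectors::mcols(win)$male_norm <- rep(1, 6)
  S4Vectors::mcols(win)$log2fm <- c(2, 1, 0.99, -1, 0, -2)
  p <- DepthProfile(win)
  calls <- classifyLog2FM(p)
  expect_equal(as.character(calls$call),
               c("W", "W", "ambiguous", "Z", "autosomal", "ambiguous"))
})

test_that("raising the W threshold never increases the number of W calls", {
  layout <- small_layout()
  prof <- normalizeDepth(
    simulateDepthProfiles(layout, dispersion = 10, seed = 5))
  thresholds <- c(0.5, 1, 1.5, 2, 2.5)
  nW <- vapply(thresholds, function(th)
    sum(classifyLog2FM(prof, wThreshold = th)$call == "W"), numeric(1))
  expect_true(all(diff(nW) <= 0))
})

test_that("the IQR fence follows the type-7 quartile convention", {
  x <- c(rep(1, 9), 10)
  expect_equal(iqrFence(x), 1)
  expect_equal(sum(x > iqrFence(x)), 1)
  expect_equal(iqrFence(rep(2, 8)), 2)  # degenerate: nothing exceeds
})

test_that("noise-free calibration is exact for both classifiers", {
  layout <- small_layout()
  prof <- normalizeDepth(
    simulateDepthProfiles(layout, meanDepth = 30, dispersion = Inf))
  truth <- truthClass(prof)
  calLog <- calibrateCalls(classifyLog2FM(prof), truth)
  expect_equal(calLog$power, 1)
  expect_equal(calLog$false_positive_rate, 0)
  calIqr <- calibrateCalls(classifyIQR(prof), truth)
  expect_equal(calIqr$power, 1)
  expect_equal(calIqr$false_positive_rate, 0)
})

test_that("calibration arithmetic matches its definition", {
  calls <- rep(c("W", "autosomal"), c(8, 2))
  truth <- rep("W", 10)
  calls <- c(calls, rep(c("W", "autosomal"), c(5, 995)))
  truth <- c(truth, rep("autosome", 1000))
  cal <- calibrateCalls(calls, truth)
  expect_equal(cal$power, 0.8)
  expect_equal(cal$false_positive_rate, 0.005)
  expect_equal(cal$n_true, 10)
  expect_equal(cal$n_false, 1000)
  perfect <- calibrateCalls(truth, truth)
  expect_equal(perfect$power, 1)
  allW <- calibrateCalls(rep("W", 1010), truth)
  expect_equal(allW$power, 1)
  expect_equal(allW$false_positive_rate, 1)
  noW <- calibrateCalls(rep("W", 3), rep("autosome", 3))
  expect_true(is.na(noW$power))
})

test_that("scaffold rollup takes the majority call with ties ambiguous", {
  calls <- data.frame(
    chrom = c("s1", "s2", "s2", "s2", "s3", "s3"),
    call = factor(c("W", "W", "W", "Z", "W", "Z"),
                  levels = c("W", "Z", "autosomal", "ambiguous")))
  roll <- scaffoldRollup(calls)
  roll <- roll[order(roll$scaffold), ]
  expect_equal(as.character(roll$call), c("W", "W", "ambiguous"))
  expect_equal(roll$n_windows, c(1, 3, 2))
})
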