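test_that("noise-free depth simulation reproduces the copy-structure means", {
  layout <- small_layout()
  prof <- simulateDepthProfiles(layout, meanDepth = 30, dispersion = Inf)
  cls <- truthClass(prof)
  expect_true(all(femaleDepth(prof)[cls == "autosome"] == 30))
  expect_true(all(maleDepth(prof)[cls == "autosome"] == 30))
  expect_true(all(femaleDepth(prof)[cls == "Z"] == 15))
  expect_true(all(maleDepth(prof)[cls == "Z"] == 30))
  expect_true(all(femaleDepth(prof)[cls == "W"] == 15))
  expect_true(all(maleDepth(prof)[cls == "W"] == 30 * 0.125))
})

test_that("window-depth sample means converge to the analytic means", {
  layout <- GenomeLayout(data.frame(name = "chr1", class = "autosome",
                                    length = 1e8), windowSize = 1e4)
  prof <- simulateDepthProfiles(layout, meanDepth = 30, dispersion = 10,
                                seed = 1)
  expect_equal(length(depthWindows(prof)), 10000)
  expect_lt(abs(mean(femaleDepth(prof)) - 30) / 30, 0.01)
  expect_lt(abs(mean(maleDepth(prof)) - 30) / 30, 0.01)
})

test_that("depth simulation is reproducible for a fixed seed and validates input", {
  layout <- small_layout()
  a <- simulateDepthProfiles(layout, seed = 99)
  b <- simulateDepthProfiles(layout, seed = 99)
  expect_identical(femaleDepth(a), femaleDepth(b))
  expect_identical(maleDepth(a), maleDepth(b))
  expect_error(simulateDepthProfiles(layout, meanDepth = -1), "> 0")
  expect_error(simulateDepthProfiles(layout, maleWBackground = 0.6),
               "0.5")
})

test_that("zero-target gametolog pairs are identical with all-zero truth", {
  p <- simulateGametologPairs(3, 60, targetDS = 0, omega = 0.5, seed = 2)
  expect_identical(as.character(zSequences(p)), as.character(wSequences(p)))
  expect_true(all(simTruth(p)$n_syn == 0))
  expect_true(all(simTruth(p)$n_nonsyn == 0))
  expect_false(any(simTruth(p)$saturated))
})

test_that("simulated pairs hit the target dS and omega on average", {
  p <- simulateGametologPairs(20, 500, targetDS = 0.33, omega = 0.4,
                              seed = 7)
  est <- ng86(p)
  expect_false(any(est$saturated))
  expect_lt(abs(mean(est$dS) - 0.33), 0.05)
  # neutral limit: accepted nonsynonymous rate matches synonymous rate
  pn <- simulateGametologPairs(20, 400, targetDS = 0.2, omega = 1, seed = 8)
  en <- ng86(pn)
  expect_lt(abs(mean(en$omega) - 1), 0.1)
})

test_that("unreachable dS targets are flagged as saturated, not truncated", {
  expect_warning(
    p <- simulateGametologPairs(1, 50, targetDS = 3, omega = 1, seed = 1),
    "saturation")
  expect_true(simTruth(p)$saturated[1])
})

test_that("repeat simulation recovers densities, enrichment and GC", {
  layout <- small_layout(autosome = 5e5, z = 2e5, w = 2e5)
  fams <- data.frame(family = c("mdg4", "L1"),
                     density = c(0.02, 0.05),
                     gc = c(0.48, 0.36),
                     mean_length = c(400, 400),
                     autosome = c(1, 1), Z = c(1, 1), W = c(10, 1))
  sim <- simulateRepeatAnnotation(layout, fams, seed = 4)
  tr <- sim$truth
  mdg4W <- tr[tr$family == "mdg4" & tr$class == "W", ]
  expect_equal(mdg4W$target_density, 0.2)
  expect_lt(abs(mdg4W$realized_density - 0.2), 0.03)
  # per-class realized densities match targets within binomial-scale error
  expect_true(all(abs(tr$realized_density - tr$target_density) < 0.03))
  # element GC close to family GC
  ann <- sim$annotation
  mseq <- S4Vectors::mcols(ann)$sequence[
    S4Vectors::mcols(ann)$family == "mdg4"]
  expect_lt(abs(mean(gcContent(mseq)) - 0.48), 0.03)
  # no same-family overlaps within a chromosome
  for (fam in fams$family) {
    sub <- ann[S4Vectors::mcols(ann)$family == fam]
    expect_identical(length(GenomicRanges::reduce(sub)), length(sub))
  }
})

test_that("over-enriched repeat densities are rejected", {
  layout <- small_layout()
  fams <- data.frame(family = "x", density = 0.2, gc = 0.4,
                     mean_length = 300, autosome = 1, Z = 1, W = 10)
  expect_error(simulateRepeatAnnotation(layout, fams, seed = 1), ">= 1")
})

test_that("gene-depth simulation follows the copy-number arithmetic", {
  nf <- simulateGeneDepths(c(1, 2, 94), meanDepth = 30, dispersion = Inf)
  expect_equal(unname(nf$depths[, 1]), c(15, 30, 1410))
  noisy <- simulateGeneDepths(rep(94, 5), meanDepth = 30, dispersion = 10,
                              seed = 3)
  cn <- copyNumber(noisy$depths, noisy$autosomalMedian)
  expect_true(all(abs(cn$estimate$copy_number - 94) / 94 < 0.05))
  expect_error(simulateGeneDepths(integer(0)), "non-empty")
  expect_error(simulateGeneDepths(c(0, 1)), ">= 1")
})

test_that("expression-count simulation produces per-sex Poisson tables", {
  sim <- simulateExpressionCounts(c(a = 5, b = 0), c(a = 5, b = 0),
                                  nFemale = 2, nMale = 3, seed = 1)
  expect_equal(dim(sim$counts), c(2L, 5L))
  expect_equal(as.integer(table(sim$sex)[c("female", "male")]), c(2L, 3L))
  expect_true(all(sim$counts["b", ] == 0))
})
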