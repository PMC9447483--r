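test_that("GC and CpG fractions follow the ambiguity conventions", {
  expect_equal(gcContent("GCGC"), 1)
  expect_equal(cpgContent("GCGC"), 1 / 3)
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(cpgContent("ATAT"), 0)
  expect_equal(gcContent("ANCG"), 2 / 3)
  expect_equal(cpgContent("ANCG"), 1)
  expect_true(is.na(gcContent("NNNN")))
  expect_error(gcContent(""), "empty")
})

test_that("K2P distance matches the closed form and handles saturation", {
  expect_equal(k2pDistance("ACGT", "ACGT")$distance, 0)
  # 10% transitions, no transversions: d = -0.5 * log(0.8)
  el <- paste(c(rep("A", 9), "G"), collapse = "")
  cons <- strrep("A", 10)
  res <- k2pDistance(el, cons)
  expect_equal(res$P, 0.1)
  expect_equal(res$Q, 0)
  expect_equal(res$distance, -0.5 * log(0.8), tolerance = 1e-12)
  sat <- k2pDistance(strrep("C", 10), strrep("A", 10))
  expect_true(sat$saturated)
  expect_true(is.na(sat$distance))
  expect_error(k2pDistance("AC", "ACG"), "equal length")
})

test_that("CpG correction excludes consensus CpG sites", {
  cons <- "CGCGCGCG"
  res <- k2pDistance("TATATATA", cons, cpgCorrect = TRUE)
  expect_equal(res$n_sites, 0L)
  expect_true(is.na(res$distance))
  # non-CpG consensus sites survive correction
  res2 <- k2pDistance("ATCGAT", "ATCGAA", cpgCorrect = TRUE)
  expect_equal(res2$n_sites, 4L)
})

test_that("window composition merges same-family overlaps and clips to windows", {
  genome <- Biostrings::DNAStringSet(c(chr = strrep("A", 1000)))
  rep1 <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(start = c(1, 201, 301), end = c(500, 400, 450)))
  S4Vectors::mcols(rep1)$family <- c("f1", "f1", "f1")
  wc <- windowComposition(genome, 1000, rep1)
  # merged f1 span is 1..500 -> 50% of the window
  expect_equal(wc$repeat_f1, 0.5)
  expect_equal(wc$repeat_total, 0.5)
  covered <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 1000))
  S4Vectors::mcols(covered)$family <- "f2"
  wc2 <- windowComposition(genome, 1000, covered)
  expect_equal(wc2$repeat_f2, 1)
  expect_error(windowComposition(genome, 0), "> 0")
  bad <- GenomicRanges::GRanges("chr", IRanges::IRanges(900, 1200))
  S4Vectors::mcols(bad)$family <- "f1"
  expect_error(windowComposition(genome, 1000, bad), "beyond")
})

test_that("terminal short windows are retained, flagged and correctly measured", {
  genome <- Biostrings::DNAStringSet(c(chr = paste0(strrep("A", 1000),
                                                    strrep("G", 500))))
  wc <- windowComposition(genome, 1000)
  expect_equal(nrow(wc), 2)
  expect_equal(wc$short, c(FALSE, TRUE))
  expect_equal(wc$length, c(1000, 500))
  expect_equal(wc$gc, c(0, 1))
})

test_that("window statistics are invariant to scaffold input order", {
  set.seed(9)
  s1 <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  g1 <- Biostrings::DNAStringSet(c(a = s1, b = s2))
  g2 <- Biostrings::DNAStringSet(c(b = s2, a = s1))
  w1 <- windowComposition(g1, 1000)
  w2 <- windowComposition(g2, 1000)
  w1 <- w1[order(w1$chrom, w1$start), ]
  w2 <- w2[order(w2$chrom, w2$start), ]
  rownames(w1) <- rownames(w2) <- NULL
  expect_equal(w1, w2)
})

test_that("composition tests separate classes with distinct GC", {
  set.seed(10)
  rec <- data.frame(
    gc = c(rnorm(500, 0.36, 0.04), rnorm(500, 0.44, 0.04)),
    cpg = rnorm(1000, 0.02, 0.002),
    repeat_total = runif(1000, 0, 0.5),
    class = rep(c("autosome", "W"), each = 500))
  res <- compositionTests(rec)
  gcRow <- res$pairwise[res$pairwise$metric == "gc", ]
  expect_lt(gcRow$p_value, 1e-10)
  same <- rec
  same$gc <- rep(rnorm(500, 0.4, 0.01), 2)
  resSame <- compositionTests(same)
  expect_gt(resSame$pairwise[resSame$pairwise$metric == "gc", "p_value"],
            0.9)
  withEmpty <- rbind(rec, transform(rec[1, ], class = "Z", gc = NA))
  withEmpty <- withEmpty[withEmpty$class != "Z", ]
  withEmpty$class <- factor(withEmpty$class,
                            levels = c("autosome", "W", "Z"))
  expect_warning(compositionTests(withEmpty), "empty class")
})

test_that("repeat/GC association finds monotone and null relationships", {
  set.seed(11)
  n <- 200
  fam <- runif(n)
  rec <- data.frame(gc = 0.3 + 0.2 * fam, cpg = runif(n),
                    repeat_total = fam + runif(n, 0, 0.2))
  rec$repeat_mdg4 <- fam
  res <- repeatGcAssociation(rec, "mdg4")
  expect_equal(res$r, 1)
  # independent columns: |r| small with high probability
  nullRejections <- 0L
  for (i in 1:20) {
    r2 <- data.frame(gc = runif(1000), cpg = runif(1000),
                     repeat_total = runif(1000))
    r2$repeat_x <- runif(1000)
    if (abs(repeatGcAssociation(r2, "x")$r) >= 0.1)
      nullRejections <- nullRejections + 1L
  }
  expect_lte(nullRejections, 1L)
  const <- rec
  const$repeat_mdg4 <- 0.5
  expect_warning(out <- repeatGcAssociation(const, "mdg4"), "constant")
  expect_true(is.na(out$r))
  expect_error(repeatGcAssociation(rec[1:5, ], "mdg4"), "10")
})
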