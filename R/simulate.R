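# Synthetic-data generators. These emulate the statistical structure a
# female-heterogametic genome imposes on comparative read-depth data, on
# gametolog codon alignments, and on repeat landscapes, so the downstream
# classifiers and estimators can be exercised and calibrated end to end.

.setSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# negative-binomial depth draw; dispersion is the NB size parameter and the
# Inf limit collapses to the (noise-free) mean
.rdepth <- function(n, mu, size) {
  if (is.infinite(size)) return(rep(mu, length.out = n))
  rnbinom(n, mu = mu, size = size)
}

#' Simulate female/male read-depth profiles over a genome layout
#'
#' Per-window expected depths follow the copy structure of a ZW genome for a
#' diploid autosomal mean of `meanDepth`: females see the full mean on
#' autosomes/PAR and half of it on the hemizygous Z and W; males see the full
#' mean on autosomes/PAR and Z, and `maleWBackground * meanDepth` of spurious
#' background mapping on the W.  Counts are drawn negative-binomially with
#' the given `dispersion` (size) parameter; `dispersion = Inf` gives the
#' noise-free limit.
#'
#' The default `maleWBackground = 0.125` makes a noise-free W window sit at
#' log2FM = log2(0.5 / 0.125) = 2, the canonical W expectation.
#'
#' @param layout A [GenomeLayout-class].
#' @param meanDepth Mean depth (reads/bp) of a diploid autosomal window; > 0.
#' @param dispersion Negative-binomial size parameter (larger = less noise;
#'   `Inf` = deterministic means).
#' @param maleWBackground Fraction of `meanDepth` spuriously mapped to W
#'   windows in the male; in `[0, 0.5)`.
#' @param seed Optional integer seed for reproducibility.
#' @return A [DepthProfile-class] whose windows carry `female_depth`,
#'   `male_depth` and `truth_class`.
#' @examples
#' layout <- GenomeLayout(data.frame(
#'   name = c("chr1", "chrZ", "chrW"),
#'   class = c("autosome", "Z", "W"),
#'   length = c(5e5, 1e5, 5e4)), windowSize = 1e4)
#' simulateDepthProfiles(layout, meanDepth = 30, dispersion = 10, seed = 1)
#' @export
simulateDepthProfiles <- function(layout, meanDepth = 30, dispersion = 10,
                                  maleWBackground = 0.125, seed = NULL) {
  stopifnot(is(layout, "GenomeLayout"))
  if (!is.numeric(meanDepth) || meanDepth <= 0)
    stop("'meanDepth' must be > 0")
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("'dispersion' must be > 0 (Inf for the noise-free limit)")
  if (maleWBackground < 0 || maleWBackground >= 0.5)
    stop("'maleWBackground' must be in [0, 0.5)")
  .setSeed(seed)
  win <- layoutWindows(layout)
  cls <- S4Vectors::mcols(win)$class
  fMult <- ifelse(cls %in% c("autosome", "PAR"), 1, 0.5)
  mMult <- ifelse(cls %in% c("autosome", "PAR", "Z"), 1, maleWBackground)
  n <- length(win)
  S4Vectors::mcols(win)$female_depth <- .rdepth(n, meanDepth * fMult, dispersion)
  S4Vectors::mcols(win)$male_depth <- .rdepth(n, meanDepth * mMult, dispersion)
  S4Vectors::mcols(win)$truth_class <- cls
  DepthProfile(win, params = list(mean_depth = meanDepth,
                                  dispersion = dispersion,
                                  male_w_background = maleWBackground,
                                  seed = seed))
}

.senseCodons <- function() {
  tb <- .ng86Tables()
  tb$codons[!tb$isStop]
}

#' Simulate gametolog codon-alignment pairs with controlled dS and omega
#'
#' Each pair starts from a random stop-free codon sequence (the Z copy); the
#' W copy is evolved by proposing uniform single-nucleotide changes and
#' accepting synonymous proposals with probability 1 and nonsynonymous
#' proposals with probability `omega` (proposals creating a stop codon are
#' discarded).  Proposals continue until the realized NG86 synonymous
#' divergence of the pair reaches `targetDS`, tracked incrementally, so the
#' realized per-pair dS sits at the target up to one substitution's
#' granularity.  Pairs that fail to reach the target before saturating are
#' flagged, never silently truncated.
#'
#' @param nPairs Number of gametolog pairs.
#' @param codonsPerGene Codons per alignment (>= 50).
#' @param targetDS Target NG86 synonymous divergence, in `[0, 3]`.
#' @param omega Acceptance probability for nonsynonymous proposals (the
#'   target dN/dS); > 0.
#' @param stratumLabel Label recorded on every pair.
#' @param zPositionRange Range (bp) from which Z anchor positions are drawn
#'   uniformly.
#' @param seed Optional integer seed.
#' @return A [GametologAlignments-class]; `simTruth()` holds per-pair counts
#'   of accepted synonymous/nonsynonymous changes, the realized incremental
#'   dS and a `saturated` flag.
#' @export
simulateGametologPairs <- function(nPairs, codonsPerGene, targetDS, omega,
                                   stratumLabel = "stratum",
                                   zPositionRange = c(0, 1e8),
                                   seed = NULL) {
  if (codonsPerGene < 50) stop("'codonsPerGene' must be >= 50")
  if (targetDS < 0 || targetDS > 3) stop("'targetDS' must be in [0, 3]")
  if (omega <= 0) stop("'omega' must be > 0")
  .setSeed(seed)
  tb <- .ng86Tables()
  sense <- .senseCodons()
  bases <- c("A", "C", "G", "T")
  gc <- Biostrings::GENETIC_CODE

  zOut <- wOut <- character(nPairs)
  truth <- data.frame(gene = sprintf("gene%03d", seq_len(nPairs)),
                      n_syn = 0L, n_nonsyn = 0L,
                      realized_dS = 0, saturated = FALSE)

  maxProposals <- max(2000L, 600L * codonsPerGene)

  for (g in seq_len(nPairs)) {
    z <- sample(sense, codonsPerGene, replace = TRUE)
    w <- z
    iz <- match(z, tb$codons)
    iw <- iz
    S <- sum(tb$synSites[z])            # per-sequence synonymous sites
    Spair <- S                           # both sequences identical initially
    SdTot <- 0
    nSyn <- nNonsyn <- 0L
    dS <- 0
    proposals <- 0L
    while (dS < targetDS && proposals < maxProposals) {
      proposals <- proposals + 1L
      cdIdx <- sample.int(codonsPerGene, 1L)
      pos <- sample.int(3L, 1L)
      cur <- w[cdIdx]
      curBase <- substr(cur, pos, pos)
      alt <- sample(setdiff(bases, curBase), 1L)
      nxt <- cur
      substr(nxt, pos, pos) <- alt
      if (gc[[nxt]] == "*") next
      syn <- gc[[nxt]] == gc[[cur]]
      if (!syn && runif(1) > omega) next
      # accept: update incremental NG86 state
      iNew <- match(nxt, tb$codons)
      SdTot <- SdTot + tb$Sd[iz[cdIdx], iNew] - tb$Sd[iz[cdIdx], iw[cdIdx]]
      Spair <- Spair + (tb$synSites[[nxt]] - tb$synSites[[w[cdIdx]]]) / 2
      w[cdIdx] <- nxt
      iw[cdIdx] <- iNew
      if (syn) nSyn <- nSyn + 1L else nNonsyn <- nNonsyn + 1L
      pS <- SdTot / Spair
      dS <- if (pS >= 0.75) Inf else -0.75 * log(1 - 4 * pS / 3)
      if (is.infinite(dS) && targetDS < Inf && pS >= 0.75) break
    }
    saturated <- dS < targetDS || is.infinite(dS)
    if (is.infinite(dS)) dS <- NA_real_
    if (saturated)
      warning(sprintf("pair %d did not reach target dS %.3g (saturation)",
                      g, targetDS))
    zOut[g] <- paste(z, collapse = "")
    wOut[g] <- paste(w, collapse = "")
    truth$n_syn[g] <- nSyn
    truth$n_nonsyn[g] <- nNonsyn
    truth$realized_dS[g] <- dS
    truth$saturated[g] <- saturated
  }

  GametologAlignments(
    geneID = truth$gene, zSeq = zOut, wSeq = wOut,
    zPosition = sort(runif(nPairs, zPositionRange[1], zPositionRange[2])),
    stratum = rep(stratumLabel, nPairs),
    truth = truth)
}

#' Simulate a repeat-family annotation over a genome layout
#'
#' Places non-overlapping (within family and chromosome) repeat intervals
#' uniformly along each chromosome until the class-specific target density is
#' reached.  The target density of family `f` on a chromosome of class `c`
#' is `density_f * enrichment_{f,c}`.  Element sequences are drawn i.i.d.
#' with the family's GC fraction.
#'
#' @param layout A [GenomeLayout-class].
#' @param familyTable A data.frame with columns `family`, `density`
#'   (genome-wide fraction of bp, in `[0,1)`), `gc` (element GC fraction),
#'   `mean_length` (bp) and one enrichment column per chromosome class
#'   present in the layout (e.g. `autosome`, `Z`, `W`); missing class
#'   columns default to enrichment 1.
#' @param seed Optional integer seed.
#' @return A list with `annotation` (a `GRanges` with metadata `family` and
#'   `sequence`) and `truth` (a data.frame of per-class, per-family target
#'   and realized densities).
#' @export
simulateRepeatAnnotation <- function(layout, familyTable, seed = NULL) {
  stopifnot(is(layout, "GenomeLayout"),
            all(c("family", "density", "gc", "mean_length") %in%
                names(familyTable)))
  if (any(familyTable$density < 0 | familyTable$density >= 1))
    stop("family densities must be in [0, 1)")
  .setSeed(seed)
  classes <- unique(unname(layout@chromClass))
  for (cl in classes)
    if (!cl %in% names(familyTable)) familyTable[[cl]] <- 1
  if (any(as.matrix(familyTable[classes]) <= 0))
    stop("enrichment factors must be > 0")

  grl <- list()
  truth <- list()
  for (fi in seq_len(nrow(familyTable))) {
    fam <- familyTable$family[fi]
    for (chrom in names(layout@chromLengths)) {
      L <- layout@chromLengths[[chrom]]
      cl <- layout@chromClass[[chrom]]
      target <- familyTable$density[fi] * familyTable[[cl]][fi]
      if (target >= 1)
        stop(sprintf("family %s on class %s: enriched density %.3g >= 1",
                     fam, cl, target))
      targetBp <- round(target * L)
      if (targetBp <= 0) {
        truth[[length(truth) + 1L]] <- data.frame(
          family = fam, chrom = chrom, class = cl,
          target_density = target, realized_density = 0)
        next
      }
      placed <- IRanges::IRanges()
      cum <- 0
      tries <- 0L
      maxTries <- 50L * ceiling(targetBp / familyTable$mean_length[fi]) + 200L
      while (cum < targetBp && tries < maxTries) {
        tries <- tries + 1L
        len <- max(20L, rpois(1L, familyTable$mean_length[fi]))
        if (len >= L) next
        st <- floor(runif(1, 1, L - len + 1))
        cand <- IRanges::IRanges(start = st, width = len)
        if (length(placed) &&
            length(IRanges::findOverlaps(cand, placed)) > 0) next
        placed <- c(placed, cand)
        cum <- cum + len
      }
      if (length(placed)) {
        gr <- GenomicRanges::GRanges(chrom, placed)
        S4Vectors::mcols(gr)$family <- fam
        gcf <- familyTable$gc[fi]
        probs <- c(gcf / 2, gcf / 2, (1 - gcf) / 2, (1 - gcf) / 2)
        seqs <- vapply(IRanges::width(placed), function(wd)
          paste(sample(c("G", "C", "A", "T"), wd, replace = TRUE,
                       prob = probs), collapse = ""), character(1))
        S4Vectors::mcols(gr)$sequence <- seqs
        grl[[length(grl) + 1L]] <- gr
      }
      truth[[length(truth) + 1L]] <- data.frame(
        family = fam, chrom = chrom, class = cl,
        target_density = target, realized_density = cum / L)
    }
  }
  ann <- if (length(grl)) suppressWarnings(do.call(c, grl))
         else GenomicRanges::GRanges()
  GenomeInfoDb::seqlengths(ann) <-
    layout@chromLengths[GenomeInfoDb::seqlevels(ann)]
  list(annotation = sort(ann), truth = do.call(rbind, truth))
}

#' Build a genome sequence with repeat elements spliced in
#'
#' Generates a random background sequence per chromosome with the given GC
#' fraction and overwrites annotated intervals with their element sequences,
#' so window-level GC tracks the local repeat landscape the way it does in a
#' real assembly.
#'
#' @param layout A [GenomeLayout-class].
#' @param annotation The `annotation` GRanges from
#'   [simulateRepeatAnnotation()] (metadata column `sequence` required).
#' @param backgroundGC GC fraction of the non-repeat background.
#' @param seed Optional integer seed.
#' @return A [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
buildGenomeWithRepeats <- function(layout, annotation, backgroundGC = 0.36,
                                   seed = NULL) {
  stopifnot(is(layout, "GenomeLayout"))
  .setSeed(seed)
  probs <- c(backgroundGC / 2, backgroundGC / 2,
             (1 - backgroundGC) / 2, (1 - backgroundGC) / 2)
  out <- lapply(names(layout@chromLengths), function(chrom) {
    L <- layout@chromLengths[[chrom]]
    s <- sample(c("G", "C", "A", "T"), L, replace = TRUE, prob = probs)
    hits <- annotation[GenomicRanges::seqnames(annotation) == chrom]
    for (i in seq_along(hits)) {
      st <- GenomicRanges::start(hits)[i]
      en <- GenomicRanges::end(hits)[i]
      s[st:en] <- strsplit(S4Vectors::mcols(hits)$sequence[i], "")[[1]]
    }
    paste(s, collapse = "")
  })
  Biostrings::DNAStringSet(setNames(unlist(out), names(layout@chromLengths)))
}

#' Simulate per-gene female read depths for W-linked copy-number estimation
#'
#' A W-linked gene with `copyNumber` copies is expected at
#' `(copyNumber / 2) * meanDepth` in a female whose diploid autosomal mean is
#' `meanDepth` (single-copy, hemizygous genes sit at half the autosomal
#' mean).  Per-gene depth is the average of per-base negative-binomial
#' counts over `geneLength` exonic bases, which is drawn as one
#' `NB(geneLength * mu, geneLength * size) / geneLength` variate.
#'
#' @param copyNumbers Integer vector (>= 1) of true gene copy numbers.
#' @param meanDepth Diploid autosomal mean depth per female.
#' @param dispersion Per-base negative-binomial size parameter (`Inf` =
#'   noise-free).
#' @param nFemales Number of simulated females (default 4).
#' @param geneLength Exonic bases averaged per gene (default 1000).
#' @param seed Optional integer seed.
#' @return A list with `depths` (genes x females matrix of mean depths) and
#'   `autosomalMedian` (per-female autosomal median depth, here the
#'   noise-free `meanDepth`).
#' @export
simulateGeneDepths <- function(copyNumbers, meanDepth = 30, dispersion = 10,
                               nFemales = 4L, geneLength = 1000L,
                               seed = NULL) {
  if (length(copyNumbers) == 0) stop("'copyNumbers' must be non-empty")
  if (any(copyNumbers < 1) || any(copyNumbers != round(copyNumbers)))
    stop("'copyNumbers' must be integers >= 1")
  if (meanDepth <= 0) stop("'meanDepth' must be > 0")
  .setSeed(seed)
  mu <- (copyNumbers / 2) * meanDepth
  depths <- vapply(seq_len(nFemales), function(f) {
    if (is.infinite(dispersion)) return(mu)
    rnbinom(length(mu), mu = mu * geneLength,
            size = dispersion * geneLength) / geneLength
  }, numeric(length(copyNumbers)))
  depths <- matrix(depths, nrow = length(copyNumbers),
                   dimnames = list(names(copyNumbers),
                                   paste0("female", seq_len(nFemales))))
  list(depths = depths,
       autosomalMedian = setNames(rep(meanDepth, nFemales),
                                  colnames(depths)))
}

#' Simulate simple per-sex Poisson expression-count tables
#'
#' Minimal generator for exercising the detection / female-specific rules:
#' per-gene, per-sample counts are Poisson with a sex-specific mean.
#'
#' @param femaleMeans,maleMeans Per-gene expected counts in each sex.
#' @param nFemale,nMale Samples per sex.
#' @param seed Optional integer seed.
#' @return A list with `counts` (genes x samples) and `sex` (named vector
#'   mapping sample to `"female"`/`"male"`).
#' @export
simulateExpressionCounts <- function(femaleMeans, maleMeans,
                                     nFemale = 2L, nMale = 2L, seed = NULL) {
  stopifnot(length(femaleMeans) == length(maleMeans))
  .setSeed(seed)
  nG <- length(femaleMeans)
  fcols <- matrix(rpois(nG * nFemale, femaleMeans), nrow = nG)
  mcols_ <- matrix(rpois(nG * nMale, maleMeans), nrow = nG)
  counts <- cbind(fcols, mcols_)
  colnames(counts) <- c(paste0("F", seq_len(nFemale)),
                        paste0("M", seq_len(nMale)))
  rownames(counts) <- names(femaleMeans)
  sex <- setNames(rep(c("female", "male"), c(nFemale, nMale)),
                  colnames(counts))
  list(counts = counts, sex = sex)
}
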