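# Nucleotide and repeat composition: GC/CpG fractions, windowed composition
# records against a repeat annotation, CpG-corrected Kimura 2-parameter
# element ages, and the repeat-family/GC association analyses.

.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) x
  else if (is(x, "DNAString")) Biostrings::DNAStringSet(x)
  else Biostrings::DNAStringSet(as.character(x))
}

#' GC content of a sequence
#'
#' Proportion of G and C among unambiguous (A/C/G/T) bases.
#'
#' @param seq Character vector, `DNAString` or `DNAStringSet`.
#' @return Numeric vector of GC fractions; `NA` for all-ambiguous input.
#' @examples
#' gcContent("GCGC")   # 1
#' gcContent("ANCG")   # 2/3
#' @export
gcContent <- function(seq) {
  x <- .asDNAStringSet(seq)
  if (any(Biostrings::width(x) == 0)) stop("empty sequence")
  gcn <- Biostrings::letterFrequency(x, "GC")[, 1]
  acgt <- Biostrings::letterFrequency(x, "ACGT")[, 1]
  unname(ifelse(acgt > 0, gcn / acgt, NA_real_))
}

#' CpG content of a sequence
#'
#' Proportion of CG dinucleotides among unambiguous dinucleotide positions
#' (overlapping windows on a single strand; windows touching an ambiguous
#' base are excluded from numerator and denominator).
#'
#' @inheritParams gcContent
#' @return Numeric vector of CpG fractions; `NA` when no unambiguous
#'   dinucleotide positions exist.
#' @examples
#' cpgContent("GCGC")  # windows GC, CG, GC -> 1/3
#' cpgContent("ANCG")  # only window CG is unambiguous -> 1
#' @export
cpgContent <- function(seq) {
  x <- .asDNAStringSet(seq)
  if (any(Biostrings::width(x) == 0)) stop("empty sequence")
  din <- Biostrings::dinucleotideFrequency(x)
  tot <- rowSums(din)
  unname(ifelse(tot > 0, din[, "CG"] / tot, NA_real_))
}

#' Kimura 2-parameter distance between an element and its consensus
#'
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` the transition and
#' `Q` the transversion proportion over scorable (both-unambiguous) aligned
#' sites.  With `cpgCorrect = TRUE`, sites belonging to a CpG dinucleotide
#' in the consensus are excluded before computing `P` and `Q` (the
#' convention used for repeat-age landscapes, where hypermutable CpG sites
#' inflate apparent divergence).
#'
#' @param elementSeq,consensusSeq Aligned sequences of equal length.
#' @param cpgCorrect Exclude consensus-CpG sites first.
#' @return A list with `P`, `Q`, `distance`, `n_sites`, `saturated` and
#'   `cpg_corrected`.  Saturation (log argument <= 0) gives `distance = NA`
#'   and `saturated = TRUE`.
#' @export
k2pDistance <- function(elementSeq, consensusSeq, cpgCorrect = FALSE) {
  e <- strsplit(toupper(as.character(elementSeq)), "")[[1]]
  cns <- strsplit(toupper(as.character(consensusSeq)), "")[[1]]
  if (length(e) != length(cns))
    stop("element and consensus must be aligned to equal length")
  keep <- rep(TRUE, length(e))
  if (cpgCorrect && length(cns) > 1) {
    isCpG <- which(cns[-length(cns)] == "C" & cns[-1] == "G")
    keep[unique(c(isCpG, isCpG + 1L))] <- FALSE
  }
  ok <- keep & e %in% c("A", "C", "G", "T") & cns %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0)
    return(list(P = NA_real_, Q = NA_real_, distance = NA_real_,
                n_sites = 0L, saturated = FALSE, cpg_corrected = cpgCorrect))
  e <- e[ok]; cns <- cns[ok]
  diffs <- e != cns
  purine <- c("A", "G")
  transition <- diffs & ((e %in% purine) == (cns %in% purine))
  P <- sum(transition) / n
  Q <- sum(diffs & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0)
    return(list(P = P, Q = Q, distance = NA_real_, n_sites = n,
                saturated = TRUE, cpg_corrected = cpgCorrect))
  list(P = P, Q = Q, distance = -0.5 * log(arg1 * sqrt(arg2)),
       n_sites = n, saturated = FALSE, cpg_corrected = cpgCorrect)
}

#' Windowed composition records against a repeat annotation
#'
#' Tiles each sequence into `windowSize` windows (terminal short windows are
#' retained and flagged) and computes per-window GC, CpG, total repeat
#' fraction and per-family repeat fractions.  Overlapping intervals of the
#' same family are merged before fractions are computed; different families
#' may double-count shared bases, so per-family fractions are bounded by the
#' total but their sum need not be.
#'
#' @param genome A [Biostrings::DNAStringSet] (names = chromosomes).
#' @param windowSize Window width in bp; > 0.
#' @param repeats Optional `GRanges` with a `family` metadata column.
#' @param classLabels Optional named vector mapping chromosome to class,
#'   added as a `class` column.
#' @return A data.frame with one row per window: `chrom`, `start`, `end`
#'   (0-based half-open), `length`, `short` (terminal flag), `gc`, `cpg`,
#'   `repeat_total` and one `repeat_<family>` column per family.
#' @export
windowComposition <- function(genome, windowSize, repeats = NULL,
                              classLabels = NULL) {
  if (windowSize <= 0) stop("'windowSize' must be > 0")
  genome <- .asDNAStringSet(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  sl <- setNames(Biostrings::width(genome), names(genome))
  tiles <- GenomicRanges::tileGenome(sl, tilewidth = windowSize,
                                     cut.last.tile.in.chrom = TRUE)
  if (!is.null(repeats)) {
    if (!"family" %in% names(S4Vectors::mcols(repeats)))
      stop("'repeats' must carry a 'family' metadata column")
    bad <- GenomicRanges::end(repeats) >
      sl[as.character(GenomicRanges::seqnames(repeats))]
    if (any(bad, na.rm = TRUE))
      stop("repeat annotation extends beyond its sequence")
  }

  rows <- lapply(names(genome), function(chrom) {
    w <- tiles[GenomicRanges::seqnames(tiles) == chrom]
    v <- Biostrings::Views(genome[[chrom]], GenomicRanges::ranges(w))
    gcn <- Biostrings::letterFrequency(v, "GC")[, 1]
    acgt <- Biostrings::letterFrequency(v, "ACGT")[, 1]
    din <- Biostrings::dinucleotideFrequency(v)
    data.frame(chrom = chrom,
               start = GenomicRanges::start(w) - 1L,
               end = GenomicRanges::end(w),
               length = GenomicRanges::width(w),
               short = GenomicRanges::width(w) < windowSize,
               gc = ifelse(acgt > 0, gcn / acgt, NA_real_),
               cpg = ifelse(rowSums(din) > 0, din[, "CG"] / rowSums(din),
                            NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  winGR <- GenomicRanges::GRanges(out$chrom,
                                  IRanges::IRanges(out$start + 1L, out$end))
  overlapFraction <- function(ann) {
    red <- GenomicRanges::reduce(ann)
    hits <- GenomicRanges::findOverlaps(winGR, red)
    ov <- GenomicRanges::pintersect(winGR[S4Vectors::queryHits(hits)],
                                    red[S4Vectors::subjectHits(hits)])
    bp <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    res <- numeric(length(winGR))
    res[as.integer(names(bp))] <- bp
    res / out$length
  }
  if (!is.null(repeats) && length(repeats)) {
    out$repeat_total <- overlapFraction(repeats)
    for (fam in unique(S4Vectors::mcols(repeats)$family))
      out[[paste0("repeat_", fam)]] <-
        overlapFraction(repeats[S4Vectors::mcols(repeats)$family == fam])
  } else {
    out$repeat_total <- 0
  }
  if (!is.null(classLabels)) out$class <- unname(classLabels[out$chrom])
  out
}

#' Pairwise composition comparisons across chromosome classes
#'
#' Class means/SDs plus two-sided Mann-Whitney U tests for each metric and
#' each pair of classes.
#'
#' @param records [windowComposition()] output (or any data.frame).
#' @param classCol Name of the class column.
#' @param metrics Columns to compare.
#' @return A list with `summary` and `pairwise` data.frames.
#' @export
compositionTests <- function(records, classCol = "class",
                             metrics = c("gc", "cpg", "repeat_total")) {
  cl <- records[[classCol]]
  if (!is.factor(cl)) cl <- factor(cl)
  empty <- levels(cl)[tabulate(cl, nlevels(cl)) == 0]
  if (length(empty)) {
    warning("empty class(es) excluded: ", paste(empty, collapse = ", "))
    cl <- droplevels(cl)
  }
  if (nlevels(cl) < 2) stop("need at least 2 classes")
  summ <- do.call(rbind, lapply(levels(cl), function(s) {
    row <- data.frame(class = s, n = sum(cl == s))
    for (m in metrics) {
      v <- records[[m]][cl == s]
      row[[paste0("mean_", m)]] <- mean(v, na.rm = TRUE)
      row[[paste0("sd_", m)]] <- sd(v, na.rm = TRUE)
    }
    row
  }))
  combs <- utils::combn(levels(cl), 2)
  pw <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- records[[m]][cl == combs[1, i]]
      b <- records[[m]][cl == combs[2, i]]
      wt <- suppressWarnings(wilcox.test(a, b))
      data.frame(metric = m, class_a = combs[1, i], class_b = combs[2, i],
                 U = unname(wt$statistic), p_value = wt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(summary = summ, pairwise = pw)
}

# rank-based partial correlation of x and y given the columns of z,
# from the inverse of the Spearman correlation matrix
.partialSpearman <- function(x, y, z) {
  m <- cbind(x, y, z)
  if (any(apply(m, 2, function(col) length(unique(col[!is.na(col)])) < 2)))
    return(list(r = NA_real_, p = NA_real_))
  rm_ <- apply(m, 2, rank)
  cm <- stats::cor(rm_)
  pm <- tryCatch(solve(cm), error = function(e) NULL)
  if (is.null(pm))   # collinear ranks: partial correlation undefined
    return(list(r = NA_real_, p = NA_real_))
  r <- -pm[1, 2] / sqrt(pm[1, 1] * pm[2, 2])
  n <- nrow(m)
  k <- ncol(m) - 2L
  tstat <- r * sqrt((n - 2 - k) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2 - k))
}

#' Association between a repeat family's density and window GC
#'
#' Spearman rank correlation between the per-window fraction of a focal
#' repeat family (e.g. the GC-rich mdg4 LTR family) and window GC content;
#' a rank-based partial correlation controlling for CpG content and the
#' non-focal repeat fraction; and the control correlation between GC and the
#' non-focal repeat fraction alone (the family-excluded null check).
#'
#' @param records [windowComposition()] output; needs `gc`, `cpg`,
#'   `repeat_total` and the focal family column.
#' @param family Focal family name (column `repeat_<family>`).
#' @return A list with `r`, `p` (Spearman), `partial_r`, `partial_p`
#'   (controlling CpG and other-repeat fraction), `control_r`, `control_p`
#'   (GC vs non-focal repeats) and `n`.
#' @export
repeatGcAssociation <- function(records, family) {
  col <- paste0("repeat_", family)
  if (!col %in% names(records)) stop("no column ", col, " in records")
  if (nrow(records) < 10) stop("need at least 10 records")
  fam <- records[[col]]
  gcv <- records$gc
  other <- records$repeat_total - fam
  ok <- complete.cases(fam, gcv, records$cpg, other)
  fam <- fam[ok]; gcv <- gcv[ok]; cpgv <- records$cpg[ok]; other <- other[ok]
  if (length(unique(fam)) < 2 || length(unique(gcv)) < 2) {
    warning("constant column; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, partial_r = NA_real_,
                partial_p = NA_real_, control_r = NA_real_,
                control_p = NA_real_, n = length(fam)))
  }
  ct <- suppressWarnings(cor.test(fam, gcv, method = "spearman"))
  part <- .partialSpearman(fam, gcv, cbind(cpg = cpgv, other = other))
  ctrl <- if (length(unique(other)) < 2) list(estimate = NA_real_,
                                              p.value = NA_real_)
          else suppressWarnings(cor.test(other, gcv, method = "spearman"))
  list(r = unname(ct$estimate), p = ct$p.value,
       partial_r = part$r, partial_p = part$p,
       control_r = unname(ctrl$estimate), control_p = ctrl$p.value,
       n = length(fam))
}
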