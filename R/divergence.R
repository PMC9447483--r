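# Gametolog divergence analysis: dS filtering, stratum assignment along the
# Z anchor, the sex-specific rate model converting dS to divergence time, and
# the GC3 gene-conversion comparison.

#' Filter gametolog divergence pairs on dS
#'
#' Retains pairs with `minDS <= dS <= maxDS` (boundaries inclusive; the
#' working range excludes near-zero alignment artifacts below 0.001 and
#' saturating pairs above 2).  Saturated pairs (undefined dS) are dropped
#' with a message.
#'
#' @param pairs A data.frame from [ng86()] (columns `dS`, `saturated`).
#' @param minDS,maxDS Inclusive bounds on dS.
#' @return The filtered data.frame.
#' @export
filterPairs <- function(pairs, minDS = 0.001, maxDS = 2) {
  sat <- is.na(pairs$dS) | (if (is.null(pairs$saturated)) FALSE
                            else pairs$saturated)
  if (any(sat))
    message(sum(sat), " saturated pair(s) dropped (undefined dS)")
  keep <- !sat & pairs$dS >= minDS & pairs$dS <= maxDS
  nOut <- sum(!keep & !sat)
  if (nOut)
    message(nOut, " pair(s) outside dS range [", minDS, ", ", maxDS,
            "] dropped")
  pairs[keep, , drop = FALSE]
}

#' Assign gametolog pairs to evolutionary strata along the Z chromosome
#'
#' With explicit `breakpoints`, genes are binned by their Z anchor position
#' (the recommended, fully reproducible path).  With `kClusters`, 1-D
#' k-means on position (100 restarts, fixed seed) yields contiguous spatial
#' clusters.  Strata are numbered along the chromosome; `rankByDS = TRUE`
#' additionally reports the age ordering (higher mean dS = older).
#'
#' @param pairs Data.frame with `z_position` and `dS` columns.
#' @param breakpoints Increasing vector of breakpoints (bp) on the Z.
#' @param kClusters Number of spatial clusters (alternative to breakpoints).
#' @param seed,nstart k-means seeding controls.
#' @param merge Optional named list mapping superstratum labels to stratum
#'   indices, e.g. `list(older = c(1, 2), recent = 3)`.
#' @return A data.frame of `gene` (when present), `z_position`, `stratum`
#'   (factor `stratum1..k` in positional order), `mean_dS` per stratum
#'   attached as attribute `stratum_means`, and `superstratum` when `merge`
#'   is given.  Attribute `age_rank` orders strata old to young by mean dS.
#' @export
assignStrata <- function(pairs, breakpoints = NULL, kClusters = NULL,
                         seed = 1, nstart = 100, merge = NULL) {
  if (is.null(breakpoints) == is.null(kClusters))
    stop("supply exactly one of 'breakpoints' or 'kClusters'")
  z <- pairs$z_position
  if (anyNA(z)) stop("all pairs must carry a z_position")
  if (!is.null(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE))
      stop("'breakpoints' must be strictly increasing")
    idx <- findInterval(z, breakpoints) + 1L
    k <- length(breakpoints) + 1L
  } else {
    k <- kClusters
    if (k > length(z)) stop("more clusters than genes")
    set.seed(seed)
    km <- kmeans(z, centers = k, nstart = nstart)
    # renumber clusters along the chromosome so labels are positional
    ord <- order(km$centers)
    idx <- match(km$cluster, ord)
  }
  stratum <- factor(paste0("stratum", idx),
                    levels = paste0("stratum", seq_len(k)))
  out <- data.frame(pairs, stratum_assigned = stratum)
  means <- tapply(pairs$dS, stratum, mean, na.rm = TRUE)
  means <- setNames(as.numeric(means), names(means))
  attr(out, "stratum_means") <- means
  attr(out, "age_rank") <- names(sort(means, decreasing = TRUE))
  if (!is.null(merge)) {
    sup <- rep(NA_character_, nrow(out))
    for (lbl in names(merge))
      sup[idx %in% merge[[lbl]]] <- lbl
    out$superstratum <- sup
  }
  out
}

#' Lineage-specific autosomal mutation rate from ortholog divergence
#'
#' `muA = medianDS / (2 * splitTimeYears)`: synonymous divergence between two
#' lineages accrues along both branches, so the per-lineage rate halves the
#' per-pair divergence.  Summaries conventionally print the rate at 2
#' significant figures (0.94 over 167 Myr gives 2.8e-9).
#'
#' @param medianDS Median synonymous divergence between 1:1 orthologs.
#' @param splitTimeYears Divergence time of the two lineages in years.
#' @return The per-lineage rate in substitutions/site/year (unrounded).
#' @examples
#' signif(autosomalRate(0.94, 167e6), 2)   # 2.8e-9
#' @export
autosomalRate <- function(medianDS, splitTimeYears) {
  if (medianDS <= 0 || splitTimeYears <= 0)
    stop("inputs must be positive")
  medianDS / (2 * splitTimeYears)
}

#' Combined ZW divergence rate under the sex-specific rate model
#'
#' The Z-linked component is `muA * zRatio` and the W-linked component
#' `muA * femaleFraction` (the W is female-limited, so it evolves at the
#' female rate); the combined divergence rate is their sum.  When the
#' model's `rounding` is finite each component is rounded to that many
#' significant figures before summation, matching the printed arithmetic
#' 3.1e-9 + 0.7e-9 = 3.8e-9 for the default model; with `rounding = NA` the
#' exact sum is returned (e.g. 2.64e-9 + 0.6e-9 = 3.24e-9 for the squamate
#' 4-fold-degenerate rate of 2.4e-9).
#'
#' @param model A [RateModel-class].
#' @return Combined ZW divergence rate (substitutions/site/year).
#' @examples
#' sexLinkedRate(RateModel())                         # 3.8e-9
#' sexLinkedRate(RateModel(muA = 2.4e-9, rounding = NA))  # 3.24e-9
#' @export
sexLinkedRate <- function(model = RateModel()) {
  stopifnot(is(model, "RateModel"))
  zComp <- model@muA * model@zRatio
  wComp <- model@muA * model@femaleFraction
  if (!is.na(model@rounding)) {
    zComp <- signif(zComp, model@rounding)
    wComp <- signif(wComp, model@rounding)
  }
  zComp + wComp
}

#' Convert synonymous divergence to divergence time
#'
#' `time = dS / rate`, linear in dS.
#'
#' @param dS Synonymous divergence (substitutions/site); vectorized.
#' @param rate Combined divergence rate (substitutions/site/year); > 0.
#' @param unit `"years"` or `"Ma"`.
#' @return Divergence time in the requested unit.
#' @examples
#' dsToTime(0.33, 3.8e-9, unit = "Ma")    # ~86.8 -> reported 87 Ma
#' dsToTime(0.33, 3.24e-9, unit = "Ma")   # ~101.9 -> reported 102 Ma
#' @export
dsToTime <- function(dS, rate, unit = c("years", "Ma")) {
  unit <- match.arg(unit)
  if (rate <= 0) stop("'rate' must be > 0")
  years <- dS / rate
  if (unit == "Ma") years / 1e6 else years
}

#' Per-stratum divergence summary with pairwise tests
#'
#' Means, standard deviations and counts of dS and dN/dS per stratum,
#' two-sided Mann-Whitney U tests on dS for every stratum pair, and
#' Levene's test for equality of dS variances across strata.
#'
#' @param pairs Data.frame with `dS`, `omega` and a stratum column.
#' @param stratumCol Name of the stratum column (default
#'   `"stratum_assigned"`, the [assignStrata()] output).
#' @return A list with `summary` (per-stratum data.frame), `pairwise`
#'   (per-pair U statistic and p-value) and `levene` (statistic, df, p).
#' @export
stratumSummary <- function(pairs, stratumCol = "stratum_assigned") {
  st <- droplevels(factor(pairs[[stratumCol]]))
  if (nlevels(st) < 2) stop("need at least 2 strata")
  if (any(table(st) < 2)) stop("each stratum needs at least 2 genes")
  summ <- do.call(rbind, lapply(levels(st), function(s) {
    d <- pairs$dS[st == s]
    o <- if ("omega" %in% names(pairs)) pairs$omega[st == s] else NA_real_
    data.frame(stratum = s, n = length(d),
               mean_dS = mean(d, na.rm = TRUE),
               sd_dS = if (length(d) > 1) sd(d, na.rm = TRUE) else NA_real_,
               mean_omega = mean(o, na.rm = TRUE),
               sd_omega = if (length(o) > 1) sd(o, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  combs <- utils::combn(levels(st), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- pairs$dS[st == combs[1, i]]
    b <- pairs$dS[st == combs[2, i]]
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    data.frame(stratum_a = combs[1, i], stratum_b = combs[2, i],
               U = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  lev <- car::leveneTest(pairs$dS ~ st, center = mean)
  list(summary = summ, pairwise = pw,
       levene = list(statistic = lev[1, "F value"],
                     df = unname(unlist(lev["Df"])),
                     p_value = lev[1, "Pr(>F)"]))
}

#' GC content at third codon positions (GC3)
#'
#' The proportion of G or C bases among third codon positions, excluding
#' codons whose third base is ambiguous from both numerator and denominator.
#'
#' @param cds Coding sequence(s): character vector or
#'   [Biostrings::DNAStringSet]; lengths must be multiples of 3.
#' @return Numeric vector of GC3 fractions (`NA` when no unambiguous third
#'   positions exist).
#' @examples
#' gc3("ATGGCC")   # third positions G, C -> 1
#' gc3("ATTAAA")   # third positions T, A -> 0
#' @export
gc3 <- function(cds) {
  cds <- as.character(cds)
  if (any(nchar(cds) == 0)) stop("empty CDS")
  if (any(nchar(cds) %% 3L != 0L))
    stop("CDS lengths must be multiples of 3")
  vapply(cds, function(s) {
    third <- substring(s, seq(3L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    third <- toupper(third)
    ok <- third %in% c("A", "C", "G", "T")
    if (!any(ok)) return(NA_real_)
    mean(third[ok] %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Compare GC3 between matched Z and W gametologs
#'
#' Welch's two-sample t-test on the GC3 distributions plus the fraction of
#' pairs in which the W copy has strictly higher GC3 than its Z gametolog —
#' an elevated fraction is the signature of GC-biased gene conversion acting
#' on the W.
#'
#' @param x A [GametologAlignments-class], or a numeric vector of Z GC3
#'   values (then `w` must be given).
#' @param w Numeric vector of W GC3 values, parallel to `x`.
#' @return A list with `t_statistic`, `p_value`, `mean_z`, `mean_w`,
#'   `fraction_w_higher` (strict inequalities only) and `n`.
#' @export
gc3Compare <- function(x, w = NULL) {
  if (is(x, "GametologAlignments")) {
    zv <- gc3(zSequences(x))
    wv <- gc3(wSequences(x))
  } else {
    zv <- as.numeric(x)
    wv <- as.numeric(w)
  }
  if (length(zv) != length(wv)) stop("Z and W GC3 vectors must be parallel")
  ok <- complete.cases(zv, wv)
  zv <- zv[ok]; wv <- wv[ok]
  tt <- if (isTRUE(all.equal(var(zv), 0)) && isTRUE(all.equal(var(wv), 0)) &&
            isTRUE(all.equal(mean(zv), mean(wv))))
    list(statistic = c(t = 0), p.value = 1)
  else suppressWarnings(t.test(wv, zv, var.equal = FALSE))
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_z = mean(zv), mean_w = mean(wv),
       fraction_w_higher = mean(wv > zv), n = length(zv))
}
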