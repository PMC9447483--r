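# Depth-based sex-linkage classification: autosome normalization, log2FM,
# the fixed log2FM >= 1 rule and the Q3 + 1.5*IQR outlier fence, plus
# power/false-positive calibration against truth labels.

#' Per-sex autosomal median depth
#'
#' The sample median of per-window mean depths restricted to windows whose
#' label is `"autosome"`, computed separately for the female and the male
#' sample.  Even-length medians use the mean of the central pair (the usual
#' sample-median convention).
#'
#' @param profile A [DepthProfile-class].
#' @param labels Per-window class labels; defaults to the profile's truth
#'   labels.
#' @param autosomeLabel Label(s) treated as autosomal.
#' @return Named numeric vector `c(female = ..., male = ...)`.
#' @export
autosomalMedian <- function(profile, labels = truthClass(profile),
                            autosomeLabel = "autosome") {
  stopifnot(is(profile, "DepthProfile"))
  if (is.null(labels))
    stop("no class labels available; supply per-window labels so the ",
         "autosomal windows can be identified")
  sel <- labels %in% autosomeLabel
  if (!any(sel))
    stop("no autosome-labeled windows; supply labels identifying at least ",
         "one autosomal window per sex")
  c(female = median(femaleDepth(profile)[sel]),
    male = median(maleDepth(profile)[sel]))
}

#' log2 ratio of female to male autosome-normalized depth (log2FM)
#'
#' `log2((femaleNorm + pseudocount) / (maleNorm + pseudocount))`.  The
#' expectation is 0 for autosomes, -1 for Z-linked windows in a female/male
#' comparison, and ~2 for W-linked windows (female at half the autosomal
#' mean over a male background of ~1/8).  With `pseudocount = 0` and both
#' norms 0 the value is undefined and `NA` is returned.
#'
#' @param femaleNorm,maleNorm Autosome-normalized depths (>= 0); vectorized.
#' @param pseudocount Added to both norms before the ratio (default 0).
#' @return Numeric vector of log2FM values.
#' @examples
#' log2FM(1, 1)            # autosomal expectation: 0
#' log2FM(0.5, 1)          # Z-linked expectation: -1
#' log2FM(0.5, 0.125)      # W-linked expectation: 2
#' @export
log2FM <- function(femaleNorm, maleNorm, pseudocount = 0) {
  if (any(femaleNorm < 0, na.rm = TRUE) || any(maleNorm < 0, na.rm = TRUE))
    stop("normalized depths must be >= 0")
  out <- log2((femaleNorm + pseudocount) / (maleNorm + pseudocount))
  out[femaleNorm == 0 & maleNorm == 0 & pseudocount == 0] <- NA_real_
  out
}

#' Normalize depths by the per-sex autosomal median and compute log2FM
#'
#' Adds `female_norm`, `male_norm` (depth divided by the sex's autosomal
#' median) and `log2fm` metadata columns to the profile.
#'
#' @param profile A [DepthProfile-class].
#' @param pseudocount Pseudocount on the normalized scale used in the log2FM
#'   ratio; the default 0.05 keeps W windows with zero male depth finite
#'   without disturbing the analytic expectations materially.
#' @param labels,autosomeLabel Passed to [autosomalMedian()].
#' @return The profile with normalization columns filled in.
#' @export
normalizeDepth <- function(profile, pseudocount = 0.05,
                           labels = truthClass(profile),
                           autosomeLabel = "autosome") {
  med <- autosomalMedian(profile, labels = labels,
                         autosomeLabel = autosomeLabel)
  if (any(med <= 0)) stop("autosomal median depth must be > 0 in both sexes")
  win <- depthWindows(profile)
  fn <- femaleDepth(profile) / med[["female"]]
  mn <- maleDepth(profile) / med[["male"]]
  S4Vectors::mcols(win)$female_norm <- fn
  S4Vectors::mcols(win)$male_norm <- mn
  S4Vectors::mcols(win)$log2fm <- log2FM(fn, mn, pseudocount)
  DepthProfile(win, params = c(profile@params,
                               list(pseudocount = pseudocount,
                                    autosomal_median = med)))
}

.callLevels <- c("W", "Z", "autosomal", "ambiguous")

#' Classify windows by the log2FM threshold rule
#'
#' A window is called W when its log2FM is at or above `wThreshold` (the
#' conservative `log2FM >= 1` rule); otherwise Z when log2FM falls in
#' `zBand` (around the Z expectation of -1), autosomal when in
#' `autosomeBand` (around 0), else ambiguous.  `NA` log2FM values are
#' ambiguous.
#'
#' @param profile A normalized [DepthProfile-class] (see [normalizeDepth()]).
#' @param wThreshold W call threshold on log2FM (call is `>=`; default 1).
#' @param zBand,autosomeBand Closed intervals for the Z and autosomal calls.
#' @return A data.frame with `chrom`, `start`, `end`, `call` (factor with
#'   levels W/Z/autosomal/ambiguous) and `method = "log2fm"`.
#' @export
classifyLog2FM <- function(profile, wThreshold = 1,
                           zBand = c(-1.5, -0.5),
                           autosomeBand = c(-0.25, 0.25)) {
  l2 <- log2FMValues(profile)
  if (is.null(l2))
    stop("profile has no log2fm column; run normalizeDepth() first")
  call <- rep("ambiguous", length(l2))
  inBand <- function(x, b) !is.na(x) & x >= b[1] & x <= b[2]
  call[inBand(l2, autosomeBand)] <- "autosomal"
  call[inBand(l2, zBand)] <- "Z"
  call[!is.na(l2) & l2 >= wThreshold] <- "W"
  win <- depthWindows(profile)
  data.frame(chrom = as.character(GenomicRanges::seqnames(win)),
             start = GenomicRanges::start(win) - 1L,
             end = GenomicRanges::end(win),
             call = factor(call, levels = .callLevels),
             method = "log2fm", stringsAsFactors = FALSE)
}

#' Tukey outlier fence Q3 + 1.5 * IQR
#'
#' Quartiles use linear interpolation between order statistics (R's type-7
#' convention).
#'
#' @param x Numeric vector (NAs dropped).
#' @return The fence value.
#' @examples
#' iqrFence(c(rep(1, 9), 10))  # Q3 = 1, IQR = 0 -> fence 1
#' @export
iqrFence <- function(x) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Classify windows by the female-depth-proportion outlier rule
#'
#' The per-window statistic is the proportion of female read depth,
#' `female_norm / (female_norm + male_norm)` (autosomal expectation 0.5,
#' ~1/3 for Z-linked windows, high for W-linked windows where male depth is
#' background only).  A window is called W when its proportion strictly
#' exceeds the Q3 + 1.5*IQR fence of the genome-wide proportion
#' distribution; all other windows are ambiguous (the rule detects only
#' W-linkage).  A degenerate all-equal distribution yields no W calls.
#'
#' @param profile A normalized [DepthProfile-class].
#' @return A data.frame as in [classifyLog2FM()], `method = "iqr"`.
#' @export
classifyIQR <- function(profile) {
  win <- depthWindows(profile)
  mc <- S4Vectors::mcols(win)
  if (is.null(mc$female_norm))
    stop("profile has no normalized depths; run normalizeDepth() first")
  if (length(win) < 4L) stop("need at least 4 windows for the IQR fence")
  tot <- mc$female_norm + mc$male_norm
  prop <- ifelse(tot > 0, mc$female_norm / tot, NA_real_)
  fence <- iqrFence(prop)
  call <- ifelse(!is.na(prop) & prop > fence, "W", "ambiguous")
  data.frame(chrom = as.character(GenomicRanges::seqnames(win)),
             start = GenomicRanges::start(win) - 1L,
             end = GenomicRanges::end(win),
             call = factor(call, levels = .callLevels),
             method = "iqr", stringsAsFactors = FALSE)
}

#' Power and false-positive rate of W calls against truth labels
#'
#' Power is the fraction of truth-W units called W; the false-positive rate
#' is the fraction of truth-non-W units called W.
#'
#' @param calls A data.frame with a `call` column ([classifyLog2FM()] /
#'   [classifyIQR()] output) or a character/factor vector of calls.
#' @param truth Per-unit truth labels; `"W"` marks true W-linkage.
#' @return A list with `power` (`NA` when there are no truth-W units),
#'   `false_positive_rate`, `n_true` and `n_false`.
#' @export
calibrateCalls <- function(calls, truth) {
  if (is.data.frame(calls)) calls <- calls$call
  calls <- as.character(calls)
  truth <- as.character(truth)
  if (length(calls) != length(truth))
    stop("'calls' and 'truth' must be parallel")
  if (anyNA(truth)) stop("every unit needs a truth label")
  isW <- truth == "W"
  nTrue <- sum(isW)
  nFalse <- sum(!isW)
  power <- if (nTrue == 0) NA_real_ else mean(calls[isW] == "W")
  fpr <- if (nFalse == 0) NA_real_ else mean(calls[!isW] == "W")
  list(power = power, false_positive_rate = fpr,
       n_true = nTrue, n_false = nFalse)
}

#' Roll per-window calls up to per-scaffold calls
#'
#' The scaffold call is the majority window call; ties between the most
#' frequent calls give `"ambiguous"` (the conservative posture).  When
#' classification was already run on per-scaffold depths there is one window
#' per scaffold and the call passes through unchanged.
#'
#' @param calls Output of [classifyLog2FM()] or [classifyIQR()]; the `chrom`
#'   column identifies the scaffold.
#' @return A data.frame with `scaffold`, `call` and `n_windows`.
#' @export
scaffoldRollup <- function(calls) {
  sp <- split(as.character(calls$call), calls$chrom)
  res <- lapply(names(sp), function(sc) {
    tab <- sort(table(sp[[sc]]), decreasing = TRUE)
    call <- if (length(tab) > 1L && tab[1] == tab[2]) "ambiguous"
            else names(tab)[1]
    data.frame(scaffold = sc, call = factor(call, levels = .callLevels),
               n_windows = length(sp[[sc]]), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
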