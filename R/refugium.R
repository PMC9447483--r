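# Refugium and toxicity statistics for transposable elements across the
# autosome / Z / W chromosome classes.

.checkTotals <- function(ungappedBp, observed) {
  if (length(ungappedBp) != length(observed) ||
      is.null(names(ungappedBp)) || is.null(names(observed)) ||
      !setequal(names(ungappedBp), names(observed)))
    stop("'ungappedBp' and 'observed' must be named vectors over the same ",
         "chromosome classes")
  observed <- observed[names(ungappedBp)]
  if (any(ungappedBp <= 0)) stop("ungapped bp must be > 0 in every class")
  if (any(observed < 0)) stop("observed totals must be >= 0")
  observed
}

#' Refugium Index per chromosome class
#'
#' Under a uniform genomic distribution, the repeat content of a chromosome
#' class is proportional to its share of ungapped sequence:
#' `expected_c = total_observed * ungapped_c / sum(ungapped)`.  The refugium
#' index `RI_c = (observed_c - expected_c) / expected_c` is positive for an
#' excess (a refugium) and negative for a depletion; a Pearson chi-square
#' statistic against the same expectation tests uniformity.  Works
#' identically whether the observed totals are repeat bp (repeat families)
#' or element counts (full-length LTRs).
#'
#' @param ungappedBp Named vector of ungapped bp per class.
#' @param observed Named vector of observed repeat bp or element counts per
#'   class (same names).
#' @return A list with `table` (class, observed, expected, ri), `chi2`,
#'   `df` and `p_value`.
#' @examples
#' refugiumIndex(c(autosome = 940e6, Z = 40e6, W = 20e6),
#'               c(autosome = 13603, Z = 1786, W = 572))
#' @export
refugiumIndex <- function(ungappedBp, observed) {
  observed <- .checkTotals(ungappedBp, observed)
  expected <- sum(observed) * ungappedBp / sum(ungappedBp)
  if (any(expected == 0))
    stop("zero expected count in a class; class too small for the test")
  if (any(expected < 5))
    warning("expected count < 5 in at least one class; chi-square ",
            "approximation may be poor")
  ri <- (observed - expected) / expected
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(table = data.frame(class = names(observed),
                          observed = unname(observed),
                          expected = unname(expected),
                          ri = unname(ri),
                          stringsAsFactors = FALSE),
       chi2 = chi2, df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Chi-square test of uniform repeat distribution across classes
#'
#' Pearson chi-square of the observed per-class totals against the
#' length-proportional expectation (df = number of classes - 1).
#'
#' @inheritParams refugiumIndex
#' @return A list with `chi2`, `df` and `p_value`.
#' @export
uniformityTest <- function(ungappedBp, observed) {
  res <- refugiumIndex(ungappedBp, observed)
  res[c("chi2", "df", "p_value")]
}

#' Toxicity Index for full-length retroelements in a ZW system
#'
#' Compares the diploid complement of (presumed transposition-competent)
#' full-length elements carried by the heterogametic female
#' (`2n_het = 2*autosomes + Z + W`) with that of the homogametic male
#' (`2n_hom = 2*autosomes + 2*Z`):
#' `index = (2n_het - 2n_hom) / 2n_hom`.  Zero indicates no sex bias;
#' positive values female-biased and negative values male-biased element
#' load.
#'
#' @param autosome,z,w Per-class element counts (or bp); >= 0.
#' @return A list with `n_het_diploid`, `n_hom_diploid` and `index`.
#' @examples
#' toxicityIndex(13603, 1786, 572)
#' @export
toxicityIndex <- function(autosome, z, w) {
  if (any(c(autosome, z, w) < 0)) stop("counts must be >= 0")
  het <- 2 * autosome + z + w
  hom <- 2 * autosome + 2 * z
  if (hom == 0) stop("2n_hom is 0; toxicity index undefined")
  list(n_het_diploid = het, n_hom_diploid = hom,
       index = (het - hom) / hom)
}

#' Per-class summary of full-length LTR retrotransposons
#'
#' Counts, percentage shares of the genome-wide total and refugium indices
#' per chromosome class.
#'
#' @param counts Named vector of fl-LTR counts per class.
#' @param ungappedBp Named vector of ungapped bp per class (same names).
#' @return A data.frame with `class`, `count`, `share_pct` (1 decimal) and
#'   `ri`; attribute `total` holds the genome-wide count.  An empty count
#'   set returns all-zero rows with a warning.
#' @export
flLtrSummary <- function(counts, ungappedBp) {
  if (sum(counts) == 0) {
    warning("no fl-LTR records; returning zero summary")
    out <- data.frame(class = names(counts), count = 0,
                      share_pct = 0, ri = NA_real_)
    attr(out, "total") <- 0
    return(out)
  }
  ri <- refugiumIndex(ungappedBp, counts)
  out <- data.frame(class = ri$table$class,
                    count = ri$table$observed,
                    share_pct = round(100 * ri$table$observed /
                                        sum(ri$table$observed), 1),
                    ri = ri$table$ri,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(counts)
  attr(out, "chi2") <- ri$chi2
  attr(out, "p_value") <- ri$p_value
  out
}

#' Per-class observed repeat bp from an annotation
#'
#' Sums merged (per-family, per-chromosome) repeat bp within each chromosome
#' class — the observed totals that feed [refugiumIndex()].
#'
#' @param annotation `GRanges` with a `family` metadata column.
#' @param chromClass Named vector mapping chromosome to class.
#' @param family Optional focal family; default sums the union of all
#'   families (same-family overlaps merged first; distinct families may
#'   share bases).
#' @return Named vector of observed bp per class.
#' @export
observedRepeatBp <- function(annotation, chromClass, family = NULL) {
  if (!is.null(family))
    annotation <- annotation[S4Vectors::mcols(annotation)$family == family]
  cls <- chromClass[as.character(GenomicRanges::seqnames(annotation))]
  out <- setNames(numeric(length(unique(chromClass))),
                  unique(unname(chromClass)))
  fams <- if (is.null(family)) unique(S4Vectors::mcols(annotation)$family)
          else family
  for (fam in fams) {
    sub <- annotation[S4Vectors::mcols(annotation)$family == fam]
    red <- GenomicRanges::reduce(sub)
    cl <- chromClass[as.character(GenomicRanges::seqnames(red))]
    bp <- tapply(GenomicRanges::width(red), cl, sum)
    out[names(bp)] <- out[names(bp)] + bp
  }
  out
}
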