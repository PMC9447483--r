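# Gene-content evolution statistics: depth-based copy number of W-linked
# genes, stratum decay rates, stratum gene-enrichment tests, translocation
# classification and raw-count expression rules.

#' Depth-based copy-number estimates for W-linked genes
#'
#' Each female's relative value is `2 * geneDepth / autosomalMedian`: the W
#' is haploid, so a single-copy W gene sits at half the diploid autosomal
#' median and the factor 2 scales single-copy genes to 1.  The copy-number
#' estimate is the mean of the per-female relative values; genes at or above
#' `duplicatedThreshold` copies are flagged as duplicated.
#'
#' @param geneDepths Genes x females matrix (or vector for one female) of
#'   mean exon depths.
#' @param autosomalMedian Per-female autosomal median depth (recycled if
#'   length 1); > 0.
#' @param duplicatedThreshold Copy-number flag threshold (default 1.5, the
#'   midpoint rounding boundary between one and two copies).
#' @return A list with `perFemale` (relative-depth matrix) and `estimate`
#'   (data.frame of `gene`, `copy_number`, `duplicated`).
#' @examples
#' copyNumber(matrix(c(15, 30), 2, 1), autosomalMedian = 30)
#' @export
copyNumber <- function(geneDepths, autosomalMedian,
                       duplicatedThreshold = 1.5) {
  if (is.vector(geneDepths)) geneDepths <- matrix(geneDepths, ncol = 1)
  nF <- ncol(geneDepths)
  if (length(autosomalMedian) == 1L)
    autosomalMedian <- rep(autosomalMedian, nF)
  if (length(autosomalMedian) != nF)
    stop("'autosomalMedian' must have one value per female")
  if (any(autosomalMedian <= 0)) stop("autosomal median must be > 0")
  rel <- 2 * sweep(geneDepths, 2, autosomalMedian, "/")
  cn <- rowMeans(rel)
  genes <- rownames(geneDepths)
  if (is.null(genes)) genes <- paste0("gene", seq_along(cn))
  list(perFemale = rel,
       estimate = data.frame(gene = genes, copy_number = unname(cn),
                             duplicated = unname(cn >= duplicatedThreshold),
                             stringsAsFactors = FALSE))
}

#' W-linked gene decay rate of a stratum
#'
#' Genes lost per year: the deficit of W genes relative to Z genes in the
#' stratum divided by the stratum's inferred divergence time.  A negative
#' deficit (more W than Z genes) is allowed but flagged as gene gain.
#'
#' @param nZ,nW Numbers of Z-linked and W-linked genes in the stratum.
#' @param timeYears Inferred divergence time of the stratum (years); > 0.
#' @return A list with `rate` (genes/year), `n_z`, `n_w`, `time_years` and
#'   `gene_gain`.
#' @examples
#' decayRate(300, 100, 40e6)   # 5e-6: five genes lost per million years
#' @export
decayRate <- function(nZ, nW, timeYears) {
  if (timeYears <= 0) stop("'timeYears' must be > 0")
  rate <- (nZ - nW) / timeYears
  list(rate = rate, n_z = nZ, n_w = nW, time_years = timeYears,
       gene_gain = rate < 0)
}

#' Fisher's exact test for stratum gene enrichment
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[W in stratum, W outside], [Z in stratum, Z outside]]`, testing whether
#' the W chromosome's genes are disproportionately retained in the stratum
#' relative to the Z gene distribution.
#'
#' @param wIn,wOut,zIn,zOut Non-negative gene counts.
#' @return A list with `odds_ratio` (conditional MLE), `p_value` and
#'   `table`.
#' @export
stratumEnrichment <- function(wIn, wOut, zIn, zOut) {
  counts <- c(wIn, wOut, zIn, zOut)
  if (any(counts < 0)) stop("counts must be >= 0")
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(c("W", "Z"), c("in_stratum", "out")))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Classify candidate autosome-to-W translocations
#'
#' A W-linked gene is a candidate translocation when it has no Z gametolog
#' and its ortholog in the outgroup genome lies off the chromosome
#' homologous to the ZW pair (for *Anolis*, chromosome 6).  Genes with a Z
#' gametolog are not translocated regardless of the ortholog hit; genes
#' without any ortholog hit remain unclassified (`"unknown"`).
#'
#' @param geneTable Data.frame with columns `z_gametolog` (gametolog id or
#'   NA) and `ortholog_chrom` (outgroup chromosome of the best hit, or NA).
#' @param ancestralChrom Outgroup chromosome homologous to the sex
#'   chromosomes (default `"6"`).
#' @return Character vector: `"translocated"`, `"not_translocated"` or
#'   `"unknown"`, parallel to the rows.
#' @export
classifyTranslocation <- function(geneTable, ancestralChrom = "6") {
  stopifnot(all(c("z_gametolog", "ortholog_chrom") %in% names(geneTable)))
  hasZ <- !is.na(geneTable$z_gametolog)
  hit <- as.character(geneTable$ortholog_chrom)
  status <- rep("unknown", nrow(geneTable))
  status[hasZ] <- "not_translocated"
  status[!hasZ & !is.na(hit) & hit == ancestralChrom] <- "not_translocated"
  status[!hasZ & !is.na(hit) & hit != ancestralChrom] <- "translocated"
  status
}

#' Raw-count expression detection and female-specific flags
#'
#' A gene is detected in a sex when it has a raw count above zero in at
#' least one sample of that sex; female-specific expression is detection in
#' females with no detection in males.  When gene lengths are supplied,
#' TPM-normalized per-sex means are added (counts divided by length, scaled
#' to one million per sample).
#'
#' @param counts Genes x samples matrix of raw counts (non-negative
#'   integers).
#' @param sex Named vector mapping each sample (column) to `"female"` or
#'   `"male"`; at least one sample per sex.
#' @param geneLengths Optional per-gene lengths (bp) enabling TPM output.
#' @param tpm Compute TPM means (default: whenever `geneLengths` given).
#' @return A data.frame with `gene`, `detected_female`, `detected_male`,
#'   `female_specific` and, with lengths, `tpm_female`, `tpm_male`.
#' @export
expressionFlags <- function(counts, sex, geneLengths = NULL,
                            tpm = !is.null(geneLengths)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(names(sex))) {
    if (length(sex) != ncol(counts)) stop("'sex' must map every sample")
    names(sex) <- colnames(counts)
  }
  sex <- sex[colnames(counts)]
  if (!all(c("female", "male") %in% sex))
    stop("need at least one sample per sex")
  fCols <- sex == "female"
  detF <- rowSums(counts[, fCols, drop = FALSE] > 0) > 0
  detM <- rowSums(counts[, !fCols, drop = FALSE] > 0) > 0
  genes <- rownames(counts)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(counts)))
  out <- data.frame(gene = genes,
                    detected_female = unname(detF),
                    detected_male = unname(detM),
                    female_specific = unname(detF & !detM),
                    stringsAsFactors = FALSE)
  if (tpm) {
    if (is.null(geneLengths))
      stop("gene lengths required for TPM normalization")
    if (length(geneLengths) != nrow(counts))
      stop("'geneLengths' must have one value per gene")
    rate <- counts / geneLengths
    tpmMat <- sweep(rate, 2, colSums(rate), "/") * 1e6
    out$tpm_female <- rowMeans(tpmMat[, fCols, drop = FALSE])
    out$tpm_male <- rowMeans(tpmMat[, !fCols, drop = FALSE])
  }
  out
}
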