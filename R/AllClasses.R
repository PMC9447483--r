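#' @import methods
#' @importFrom stats median quantile rnbinom rpois runif setNames kmeans
#'   wilcox.test fisher.test t.test chisq.test cor.test pchisq pt sd var
#'   complete.cases
#' @importFrom utils head
NULL

.CHROM_CLASSES <- c("autosome", "Z", "W", "PAR")

#' Genome layout for a female-heterogametic (ZW) genome
#'
#' Holds the chromosome partition of a (real or simulated) genome into
#' autosomes, Z, W and pseudoautosomal classes, together with a half-open,
#' 0-based window tiling. The class labels are the ground truth used by the
#' depth-classifier calibration and by the repeat-landscape generator.
#'
#' @slot windows A [GenomicRanges::GRanges] tiling of the genome; metadata
#'   column `class` carries the chromosome class of each window.
#' @slot windowSize Window width in bp (terminal windows may be shorter).
#' @slot chromLengths Named numeric vector of chromosome lengths (bp).
#' @slot chromClass Named character vector mapping chromosome to class,
#'   one of `"autosome"`, `"Z"`, `"W"`, `"PAR"`.
#'
#' @seealso [GenomeLayout()] for the constructor.
#' @export
setClass("GenomeLayout",
  representation(
    windows = "GRanges",
    windowSize = "integer",
    chromLengths = "numeric",
    chromClass = "character"
  )
)

setValidity("GenomeLayout", function(object) {
  msg <- character()
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "all chromosome lengths must be > 0")
  if (!all(object@chromClass %in% .CHROM_CLASSES))
    msg <- c(msg, sprintf("chromosome classes must be one of: %s",
                          paste(.CHROM_CLASSES, collapse = ", ")))
  if (length(object@windowSize) != 1L || object@windowSize <= 0L)
    msg <- c(msg, "windowSize must be a single positive integer")
  if (!"class" %in% names(S4Vectors::mcols(object@windows)))
    msg <- c(msg, "windows must carry a 'class' metadata column")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeLayout
#'
#' @param chromosomes A data.frame with columns `name`, `class`
#'   (one of `"autosome"`, `"Z"`, `"W"`, `"PAR"`) and `length` (bp).
#' @param windowSize Window width in bp used to tile each chromosome into
#'   0-based half-open windows (default 10000, the windowing used for
#'   comparative read-depth mapping).
#' @return A [GenomeLayout-class] object.
#' @examples
#' layout <- GenomeLayout(data.frame(
#'   name = c("chr1", "chrZ", "chrW"),
#'   class = c("autosome", "Z", "W"),
#'   length = c(1e6, 2e5, 1e5)))
#' @export
GenomeLayout <- function(chromosomes, windowSize = 10000L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "class", "length") %in% names(chromosomes)))
  windowSize <- as.integer(windowSize)
  if (is.na(windowSize) || windowSize <= 0L)
    stop("'windowSize' must be a positive integer")
  if (any(chromosomes$length <= 0))
    stop("all chromosome lengths must be > 0")
  lens <- setNames(as.numeric(chromosomes$length), chromosomes$name)
  cls <- setNames(as.character(chromosomes$class), chromosomes$name)
  if (!all(cls %in% .CHROM_CLASSES))
    stop("chromosome 'class' must be one of: ",
         paste(.CHROM_CLASSES, collapse = ", "))
  sl <- setNames(as.integer(lens), names(lens))
  tiles <- GenomicRanges::tileGenome(sl, tilewidth = windowSize,
                                     cut.last.tile.in.chrom = TRUE)
  S4Vectors::mcols(tiles)$class <- unname(cls[as.character(
    GenomeInfoDb::seqnames(tiles))])
  new("GenomeLayout", windows = tiles, windowSize = windowSize,
      chromLengths = lens, chromClass = cls)
}

#' @describeIn GenomeLayout-class the window tiling as a `GRanges`
#' @param x,object A `GenomeLayout`.
#' @export
setGeneric("layoutWindows", function(x) standardGeneric("layoutWindows"))

#' @export
setMethod("layoutWindows", "GenomeLayout", function(x) x@windows)

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout:", length(object@chromLengths), "chromosomes,",
      length(object@windows), "windows of", object@windowSize, "bp\n")
  tab <- tapply(object@chromLengths, object@chromClass[names(object@chromLengths)], sum)
  for (cl in names(tab))
    cat(sprintf("  %-9s %s bp\n", cl, format(tab[[cl]], big.mark = ",")))
})

#' Female/male read-depth profile over genomic windows
#'
#' Wraps a `GRanges` of windows (or whole scaffolds) carrying per-window mean
#' read depth for one female and one male sample, with an optional truth
#' class label for calibration.  [normalizeDepth()] adds autosome-normalized
#' depths and the log2 female:male ratio (log2FM).
#'
#' @slot windows `GRanges` with metadata columns `female_depth`,
#'   `male_depth`, optionally `truth_class`, and after normalization
#'   `female_norm`, `male_norm`, `log2fm`.
#' @slot params Named list recording simulation/normalization parameters.
#' @export
setClass("DepthProfile",
  representation(windows = "GRanges", params = "list")
)

setValidity("DepthProfile", function(object) {
  mc <- S4Vectors::mcols(object@windows)
  msg <- character()
  if (!all(c("female_depth", "male_depth") %in% names(mc)))
    msg <- c(msg, "windows must carry 'female_depth' and 'male_depth'")
  else if (any(mc$female_depth < 0, na.rm = TRUE) ||
           any(mc$male_depth < 0, na.rm = TRUE))
    msg <- c(msg, "depths must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn DepthProfile-class construct from a `GRanges` or data.frame
#' @param windows `GRanges` (or data.frame with `chrom`, `start`, `end`)
#'   with `female_depth`, `male_depth` and optionally `truth_class`.
#' @param params optional list of provenance parameters.
#' @export
DepthProfile <- function(windows, params = list()) {
  if (is.data.frame(windows)) {
    gr <- GenomicRanges::GRanges(
      seqnames = windows$chrom,
      ranges = IRanges::IRanges(start = windows$start + 1L, end = windows$end))
    for (col in setdiff(names(windows), c("chrom", "start", "end")))
      S4Vectors::mcols(gr)[[col]] <- windows[[col]]
    windows <- gr
  }
  new("DepthProfile", windows = windows, params = params)
}

#' @describeIn DepthProfile-class the underlying `GRanges`
#' @param x,object A `DepthProfile`.
#' @export
setGeneric("depthWindows", function(x) standardGeneric("depthWindows"))

#' @export
setMethod("depthWindows", "DepthProfile", function(x) x@windows)

#' @describeIn DepthProfile-class per-window female mean depth
#' @export
setGeneric("femaleDepth", function(x) standardGeneric("femaleDepth"))

#' @export
setMethod("femaleDepth", "DepthProfile",
          function(x) S4Vectors::mcols(x@windows)$female_depth)

#' @describeIn DepthProfile-class per-window male mean depth
#' @export
setGeneric("maleDepth", function(x) standardGeneric("maleDepth"))

#' @export
setMethod("maleDepth", "DepthProfile",
          function(x) S4Vectors::mcols(x@windows)$male_depth)

#' @describeIn DepthProfile-class truth class labels (or NULL)
#' @export
setGeneric("truthClass", function(x) standardGeneric("truthClass"))

#' @export
setMethod("truthClass", "DepthProfile",
          function(x) S4Vectors::mcols(x@windows)$truth_class)

#' @describeIn DepthProfile-class per-window log2FM values (after
#'   [normalizeDepth()])
#' @export
setGeneric("log2FMValues", function(x) standardGeneric("log2FMValues"))

#' @export
setMethod("log2FMValues", "DepthProfile",
          function(x) S4Vectors::mcols(x@windows)$log2fm)

setMethod("show", "DepthProfile", function(object) {
  n <- length(object@windows)
  cat("DepthProfile:", n, "windows on",
      length(GenomeInfoDb::seqlevels(object@windows)), "sequences\n")
  tc <- truthClass(object)
  if (!is.null(tc)) {
    tab <- table(tc)
    cat("  truth classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(log2FMValues(object)))
    cat(sprintf("  log2FM: median %.3f\n",
                median(log2FMValues(object), na.rm = TRUE)))
})

#' Paired Z/W gametolog codon alignments
#'
#' Parallel Z and W coding sequences for a set of gametolog pairs, each pair
#' codon-aligned (equal length, multiple of 3, no internal stop codons), with
#' optional anchor positions on the Z chromosome and stratum labels.  The
#' `truth` slot carries simulator ground truth (accepted synonymous and
#' nonsynonymous changes) when the object was generated by
#' [simulateGametologPairs()].
#'
#' @slot geneID Character vector of gene identifiers.
#' @slot zSeq,wSeq [Biostrings::DNAStringSet] of aligned CDS, parallel to
#'   `geneID`.
#' @slot zPosition Numeric anchor position of each gene on the Z (bp; NA
#'   when unanchored).
#' @slot stratum Character stratum labels (NA when unassigned).
#' @slot truth A `data.frame` of simulator truth (possibly empty).
#' @export
setClass("GametologAlignments",
  representation(
    geneID = "character",
    zSeq = "DNAStringSet",
    wSeq = "DNAStringSet",
    zPosition = "numeric",
    stratum = "character",
    truth = "data.frame"
  )
)

setValidity("GametologAlignments", function(object) {
  n <- length(object@geneID)
  msg <- character()
  if (length(object@zSeq) != n || length(object@wSeq) != n ||
      length(object@zPosition) != n || length(object@stratum) != n)
    msg <- c(msg, "all slots must be parallel to geneID")
  wz <- Biostrings::width(object@zSeq)
  ww <- Biostrings::width(object@wSeq)
  if (n > 0) {
    if (!all(wz == ww))
      msg <- c(msg, "Z and W sequences of a pair must have equal length")
    if (!all(wz %% 3L == 0L))
      msg <- c(msg, "alignment lengths must be multiples of 3")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GametologAlignments-class constructor
#' @param geneID,zSeq,wSeq,zPosition,stratum,truth see slot descriptions.
#' @export
GametologAlignments <- function(geneID, zSeq, wSeq,
                                zPosition = rep(NA_real_, length(geneID)),
                                stratum = rep(NA_character_, length(geneID)),
                                truth = data.frame()) {
  if (is.character(zSeq)) zSeq <- Biostrings::DNAStringSet(zSeq)
  if (is.character(wSeq)) wSeq <- Biostrings::DNAStringSet(wSeq)
  new("GametologAlignments", geneID = as.character(geneID),
      zSeq = zSeq, wSeq = wSeq,
      zPosition = as.numeric(zPosition), stratum = as.character(stratum),
      truth = truth)
}

#' @export
setMethod("length", "GametologAlignments", function(x) length(x@geneID))

#' @describeIn GametologAlignments-class gene identifiers
#' @param x,object A `GametologAlignments`.
#' @export
setGeneric("geneID", function(x) standardGeneric("geneID"))

#' @export
setMethod("geneID", "GametologAlignments", function(x) x@geneID)

#' @describeIn GametologAlignments-class Z-linked sequences
#' @export
setGeneric("zSequences", function(x) standardGeneric("zSequences"))

#' @export
setMethod("zSequences", "GametologAlignments", function(x) x@zSeq)

#' @describeIn GametologAlignments-class W-linked sequences
#' @export
setGeneric("wSequences", function(x) standardGeneric("wSequences"))

#' @export
setMethod("wSequences", "GametologAlignments", function(x) x@wSeq)

#' @describeIn GametologAlignments-class Z anchor positions (bp)
#' @export
setGeneric("zPosition", function(x) standardGeneric("zPosition"))

#' @export
setMethod("zPosition", "GametologAlignments", function(x) x@zPosition)

#' @describeIn GametologAlignments-class simulator truth table
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @export
setMethod("simTruth", "GametologAlignments", function(x) x@truth)

setMethod("show", "GametologAlignments", function(object) {
  cat("GametologAlignments:", length(object), "Z/W pairs")
  if (length(object))
    cat(sprintf(", %d-%d bp aligned CDS",
                min(Biostrings::width(object@zSeq)),
                max(Biostrings::width(object@zSeq))))
  cat("\n")
  if (nrow(object@truth))
    cat("  simulator truth available (", nrow(object@truth), "rows )\n")
})

#' Sex-specific mutation-rate model for ZW divergence dating
#'
#' Parameterizes the conversion of gametolog synonymous divergence to time.
#' The Z-linked component of the divergence rate is `muA * zRatio` and the
#' W-linked (female-limited) component is `muA * femaleFraction`; their sum
#' is the combined ZW divergence rate used by [dsToTime()].  `rounding`
#' gives the number of significant figures applied to each component before
#' summation ([sexLinkedRate()]); set it to `NA` for the exact sum.
#'
#' @slot muA Autosomal per-lineage mutation rate (substitutions/site/year).
#' @slot zRatio Z:autosome mutation-rate ratio (male-biased mutation).
#' @slot femaleFraction W (female-limited) rate as a fraction of `muA`.
#' @slot rounding Significant figures applied to each component (NA = exact).
#' @export
setClass("RateModel",
  representation(muA = "numeric", zRatio = "numeric",
                 femaleFraction = "numeric", rounding = "numeric")
)

setValidity("RateModel", function(object) {
  msg <- character()
  if (object@muA <= 0) msg <- c(msg, "muA must be > 0")
  if (object@zRatio <= 0) msg <- c(msg, "zRatio must be > 0")
  if (object@femaleFraction <= 0)
    msg <- c(msg, "femaleFraction must be > 0")
  if (!is.na(object@rounding) && object@rounding < 1)
    msg <- c(msg, "rounding must be >= 1 significant figure or NA")
  if (length(msg)) msg else TRUE
})

#' @describeIn RateModel-class constructor. Defaults are the snake-lineage
#'   values: autosomal rate 2.8e-9/site/year, Z:A ratio 1.1, female (W) rate
#'   one quarter of the autosomal rate, components rounded to 2 significant
#'   figures.
#' @param muA,zRatio,femaleFraction,rounding see slot descriptions.
#' @export
RateModel <- function(muA = 2.8e-9, zRatio = 1.1, femaleFraction = 0.25,
                      rounding = 2) {
  new("RateModel", muA = muA, zRatio = zRatio,
      femaleFraction = femaleFraction, rounding = as.numeric(rounding))
}

setMethod("show", "RateModel", function(object) {
  cat(sprintf(
    "RateModel: muA = %.3g, Z:A ratio = %.3g, female fraction = %.3g%s\n",
    object@muA, object@zRatio, object@femaleFraction,
    if (is.na(object@rounding)) " (exact components)"
    else sprintf(" (components at %d s.f.)", as.integer(object@rounding))))
  cat(sprintf("  combined ZW divergence rate: %.3g subs/site/year\n",
              sexLinkedRate(object)))
})
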