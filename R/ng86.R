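# Nei-Gojobori (1986) counting machinery.
#
# Site counts and pathway-averaged difference counts are precomputed over all
# 64x64 codon pairs the first time they are needed and cached for the session.
# Conventions (classic NG86):
#   * a possible change at a site is synonymous iff it preserves the amino
#     acid; changes creating a stop codon count as nonsynonymous sites;
#   * codons differing at k > 1 positions are scored by averaging syn/nonsyn
#     steps over all k! substitution orderings whose intermediates are not
#     stop codons (equal pathway weights; if every ordering passes through a
#     stop, all orderings are used and the pair is flagged);
#   * proportions are corrected with the Jukes-Cantor formula
#     d = -3/4 * log(1 - 4p/3), undefined (saturated) at p >= 3/4.

.ng86Env <- new.env(parent = emptyenv())

.ng86Tables <- function() {
  if (!is.null(.ng86Env$Sd)) return(.ng86Env)
  bases <- c("T", "C", "A", "G")
  codons <- sort(apply(expand.grid(bases, bases, bases,
                                   stringsAsFactors = FALSE), 1L, paste,
                       collapse = ""))
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  isStop <- aa == "*"

  mutate1 <- function(codon, pos, base) {
    substr(codon, pos, pos) <- base
    codon
  }

  # synonymous site count per codon (NA for stops)
  synSites <- vapply(codons, function(cd) {
    if (gc[[cd]] == "*") return(NA_real_)
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cd, pos, pos))) {
        alt <- mutate1(cd, pos, b)
        if (gc[[alt]] != "*" && gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))

  nc <- length(codons)
  Sd <- matrix(0, nc, nc, dimnames = list(codons, codons))
  Nd <- matrix(0, nc, nc, dimnames = list(codons, codons))
  noPath <- matrix(FALSE, nc, nc, dimnames = list(codons, codons))

  permList <- list(`1` = matrix(1L, 1, 1),
                   `2` = rbind(c(1L, 2L), c(2L, 1L)),
                   `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L),
                               c(2L, 1L, 3L), c(2L, 3L, 1L),
                               c(3L, 1L, 2L), c(3L, 2L, 1L)))

  stepClass <- function(from, to) {
    # both from and to are non-stop by pathway construction
    if (gc[[from]] == gc[[to]]) c(1, 0) else c(0, 1)
  }

  for (i in seq_len(nc)) {
    if (isStop[i]) next
    ci <- codons[i]
    for (j in seq_len(nc)) {
      if (isStop[j] || i == j) next
      cj <- codons[j]
      diffPos <- which(strsplit(ci, "")[[1]] != strsplit(cj, "")[[1]])
      k <- length(diffPos)
      if (k == 0L) next
      perms <- permList[[as.character(k)]]
      pathS <- pathN <- numeric(0)
      for (p in seq_len(nrow(perms))) {
        cur <- ci
        s <- n <- 0
        ok <- TRUE
        for (step in perms[p, ]) {
          pos <- diffPos[step]
          nxt <- mutate1(cur, pos, substr(cj, pos, pos))
          if (gc[[nxt]] == "*") { ok <- FALSE; break }
          cl <- stepClass(cur, nxt)
          s <- s + cl[1]; n <- n + cl[2]
          cur <- nxt
        }
        if (ok) { pathS <- c(pathS, s); pathN <- c(pathN, n) }
      }
      if (!length(pathS)) {
        # no stop-free ordering exists: fall back to all orderings,
        # scoring steps into/out of stops as nonsynonymous
        noPath[i, j] <- TRUE
        for (p in seq_len(nrow(perms))) {
          cur <- ci
          s <- n <- 0
          for (step in perms[p, ]) {
            pos <- diffPos[step]
            nxt <- mutate1(cur, pos, substr(cj, pos, pos))
            if (gc[[cur]] != "*" && gc[[nxt]] != "*" &&
                gc[[cur]] == gc[[nxt]]) s <- s + 1 else n <- n + 1
            cur <- nxt
          }
          pathS <- c(pathS, s); pathN <- c(pathN, n)
        }
      }
      Sd[i, j] <- mean(pathS)
      Nd[i, j] <- mean(pathN)
    }
  }

  .ng86Env$codons <- codons
  .ng86Env$synSites <- synSites
  .ng86Env$Sd <- Sd
  .ng86Env$Nd <- Nd
  .ng86Env$noPath <- noPath
  .ng86Env$isStop <- setNames(isStop, codons)
  .ng86Env
}

.splitCodons <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) %% 3L != 0L)
    stop("sequence length is not a multiple of 3")
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -3/4 * log(1 - 4p/3)`; returns `NA` (saturation) for `p >= 0.75`.
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance in substitutions per site.
#' @export
jukesCantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) divergence between two aligned coding sequences
#'
#' Estimates synonymous (`dS`) and nonsynonymous (`dN`) divergence between a
#' pair of codon-aligned CDS by the NG86 counting method: synonymous site
#' counts averaged over the two sequences, multi-hit codons scored by equal
#' averaging over stop-free substitution pathways, and Jukes-Cantor
#' correction of the raw proportions.  Codons containing gaps or ambiguous
#' bases in either sequence are removed pairwise before counting.
#'
#' @param seq1,seq2 Aligned CDS as character strings or
#'   [Biostrings::DNAString] objects; equal length, multiple of 3.
#' @return A one-row `data.frame` with columns `S_sites`, `N_sites`
#'   (synonymous/nonsynonymous site counts averaged over the two sequences),
#'   `Sd`, `Nd` (pathway-averaged difference counts), `pS`, `pN`
#'   (proportions), `dS`, `dN` (Jukes-Cantor corrected), `omega`
#'   (`dN/dS`, `NA` when `dS` is 0 or undefined), `n_codons` and
#'   `saturated` (`TRUE` when `pS` or `pN` is at or beyond the correction's
#'   domain).
#' @examples
#' # one synonymous third-position difference over 5 codons
#' ng86Pair("ATGGGAACCCTGTAC", "ATGGGGACCCTGTAC")
#' @export
ng86Pair <- function(seq1, seq2) {
  tb <- .ng86Tables()
  c1 <- .splitCodons(seq1)
  c2 <- .splitCodons(seq2)
  if (length(c1) != length(c2))
    stop("sequences must have equal length")
  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  c1 <- c1[clean]; c2 <- c2[clean]
  if (any(tb$isStop[c1]) || any(tb$isStop[c2]))
    stop("internal stop codon in alignment")
  nCodons <- length(c1)
  if (nCodons == 0L)
    stop("no scorable codons after gap/ambiguity removal")
  S <- (sum(tb$synSites[c1]) + sum(tb$synSites[c2])) / 2
  N <- 3 * nCodons - S
  i1 <- match(c1, tb$codons)
  i2 <- match(c2, tb$codons)
  idx <- cbind(i1, i2)
  SdTot <- sum(tb$Sd[idx])
  NdTot <- sum(tb$Nd[idx])
  pS <- SdTot / S
  pN <- NdTot / N
  dS <- jukesCantor(pS)
  dN <- jukesCantor(pN)
  saturated <- is.na(dS) || is.na(dN)
  omega <- if (!saturated && dS > 0) dN / dS else NA_real_
  data.frame(S_sites = S, N_sites = N, Sd = SdTot, Nd = NdTot,
             pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
             n_codons = nCodons, saturated = saturated)
}

#' NG86 divergence for a set of gametolog pairs
#'
#' Applies [ng86Pair()] to every Z/W pair and returns one row per gene,
#' carrying the Z anchor position and stratum label through.
#'
#' @param x A [GametologAlignments-class] object.
#' @return A `data.frame` with columns `gene`, `z_position`, `stratum` and
#'   the [ng86Pair()] columns.
#' @export
ng86 <- function(x) {
  stopifnot(is(x, "GametologAlignments"))
  zs <- as.character(zSequences(x))
  ws <- as.character(wSequences(x))
  rows <- lapply(seq_along(zs), function(i) ng86Pair(zs[i], ws[i]))
  out <- do.call(rbind, rows)
  cbind(data.frame(gene = geneID(x), z_position = zPosition(x),
                   stratum = x@stratum, stringsAsFactors = FALSE),
        out)
}
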