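# Brute-force NG86 oracle, written independently of the package internals:
# recursive depth-first enumeration of substitution pathways per codon pair,
# computed directly from the standard genetic code each time (results are
# memoised per codon pair purely for speed).

.oracleCode <- Biostrings::GENETIC_CODE
.oracleMemo <- new.env(parent = emptyenv())

oracle_syn_sites <- function(codon) {
  aa <- .oracleCode[[codon]]
  stopifnot(aa != "*")
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (.oracleCode[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# recursively walk every ordering of the remaining differing positions,
# pruning branches that pass through a stop codon; returns a matrix with one
# row (syn, nonsyn) per surviving complete pathway
oracle_walk <- function(cur, target, avoidStops = TRUE) {
  diffPos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
  if (!length(diffPos)) return(matrix(c(0, 0), 1))
  out <- NULL
  for (pos in diffPos) {
    nxt <- cur
    substr(nxt, pos, pos) <- substr(target, pos, pos)
    if (avoidStops && .oracleCode[[nxt]] == "*") next
    step <- if (.oracleCode[[cur]] != "*" && .oracleCode[[nxt]] != "*" &&
                .oracleCode[[cur]] == .oracleCode[[nxt]]) c(1, 0) else c(0, 1)
    rest <- oracle_walk(nxt, target, avoidStops)
    if (is.null(rest)) next
    out <- rbind(out, sweep(rest, 2, step, "+"))
  }
  out
}

oracle_codon_pair <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .oracleMemo[[key]]
  if (!is.null(hit)) return(hit)
  paths <- oracle_walk(c1, c2, avoidStops = TRUE)
  if (is.null(paths)) paths <- oracle_walk(c1, c2, avoidStops = FALSE)
  res <- colMeans(paths)
  .oracleMemo[[key]] <- res
  res
}

oracle_ng86 <- function(seq1, seq2) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- split3(toupper(seq1))
  c2 <- split3(toupper(seq2))
  keep <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  S <- mean(c(sum(vapply(c1, oracle_syn_sites, 1)),
              sum(vapply(c2, oracle_syn_sites, 1))))
  N <- 3 * length(c1) - S
  sd_ <- nd_ <- 0
  for (i in seq_along(c1)) {
    if (c1[i] == c2[i]) next
    sn <- oracle_codon_pair(c1[i], c2[i])
    sd_ <- sd_ + sn[1]
    nd_ <- nd_ + sn[2]
  }
  pS <- sd_ / S
  pN <- nd_ / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd_, Nd = nd_, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

# random stop-free CDS of n codons
random_cds <- function(nCodons) {
  sense <- setdiff(names(.oracleCode), c("TAA", "TAG", "TGA"))
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

# mutate a CDS at k random positions (never creating a stop codon)
mutate_cds <- function(cds, k) {
  v <- strsplit(cds, "")[[1]]
  for (i in seq_len(k)) {
    repeat {
      pos <- sample.int(length(v), 1)
      old <- v[pos]
      v[pos] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      cd <- (pos - 1) %/% 3
      codon <- paste(v[(cd * 3 + 1):(cd * 3 + 3)], collapse = "")
      if (.oracleCode[[codon]] != "*") break
      v[pos] <- old
    }
  }
  paste(v, collapse = "")
}
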