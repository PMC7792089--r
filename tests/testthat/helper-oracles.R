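# Independent oracles used across the suite.  These deliberately avoid the
# package's internal code paths: plain R loops and brute-force enumeration.

# step-by-step routing oracle: literal transcription of the algorithm for
# one output capsule (couplings softmaxed over the n inputs)
oracleRouting <- function(u, T) {
  n <- ncol(u)
  b <- rep(0, n)
  v <- NULL
  for (t in seq_len(T)) {
    cpl <- exp(b) / sum(exp(b))
    a <- as.numeric(u %*% cpl)
    r2 <- sum(a^2)
    v <- if (r2 == 0) a * 0 else (r2 / (1 + r2)) * a / sqrt(r2)
    b <- b + as.numeric(crossprod(u, v))
  }
  v
}

# brute-force AUC over all positive-negative pairs, ties counting 1/2
oracleAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# dinucleotide counts by direct substring tabulation
oracleDinucCounts <- function(s) {
  chars <- strsplit(s, "")[[1]]
  paste0(chars[-length(chars)], chars[-1])
}

# type-7 (linear interpolation) quartiles written out by hand, then the
# Tukey upper fence
oracleUpperFence <- function(x) {
  x <- sort(x)
  n <- length(x)
  q7 <- function(p) {
    hh <- (n - 1) * p + 1
    lo <- floor(hh)
    hi <- ceiling(hh)
    x[lo] + (hh - lo) * (x[hi] - x[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75)
  q3 + 1.5 * (q3 - q1)
}

randomSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                               collapse = "")

# best ungapped alignment of a motif against a consensus, overhangs
# allowed (the usual motif-alignment convention): maximum number of
# matching positions over all offsets
consensusMatches <- function(consensus, motif) {
  w <- nchar(motif); h <- nchar(consensus)
  mchars <- strsplit(motif, "")[[1]]
  cchars <- strsplit(consensus, "")[[1]]
  best <- 0L
  for (o in seq(-(w - 1L), h - 1L)) {      # motif start minus 1 on consensus
    mIdx <- seq_len(w)
    cIdx <- o + mIdx
    keep <- cIdx >= 1L & cIdx <= h
    if (!any(keep)) next
    best <- max(best, sum(mchars[keep] == cchars[cIdx[keep]]))
  }
  best
}

# training configuration used for the synthetic planted-motif benchmark
benchmarkModelArgs <- list(nFilters = 64L)
benchmarkTrainArgs <- list(epochs = 15L, lr = 0.003, patience = 3L)
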