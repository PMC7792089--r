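#' Extract detector-selected subsequences
#'
#' The convolution detectors act as motif detectors: for each detector
#' and each positive fragment, if any feature-map position responds
#' (\eqn{conf_i > 0}) the subsequence of width h starting at the argmax
#' position (leftmost on ties) is extracted.  Detectors that never
#' respond contribute empty lists.
#'
#' @param model a trained \linkS4class{CapsModel}.
#' @param positives character vector / \code{DNAStringSet} of positive
#'   fragments, or a \linkS4class{BindingSiteSet} (its positive records
#'   are used); fragments are centre-padded to the model length.
#' @return list of character vectors, one per detector.
#' @export
extractSubsequences <- function(model, positives) {
  cfg <- model@config
  if (is(positives, "BindingSiteSet")) {
    positives <- as.character(positives@sequences[positives@label == "positive"])
  } else if (is(positives, "XStringSet")) {
    positives <- as.character(positives)
  }
  padded <- vapply(positives, function(s) {
    p <- padOrDiscard(s, lengthPolicy(cfg$L))
    if (is.null(p)) stop("a fragment is longer than the model's fragment length")
    p
  }, character(1))
  codes <- .codesMatrix(padded)
  sc <- .convScanCpp(codes, .weightsList(model), cfg)
  lapply(seq_len(cfg$K), function(k) {
    hit <- sc$max[, k] > 0
    if (!any(hit)) return(character(0))
    starts <- sc$argmax[hit, k]
    substring(padded[hit], starts, starts + cfg$h - 1L)
  })
}

#' Build a position frequency matrix
#'
#' Stacks equal-length subsequences into per-column base counts.
#' Padding characters \code{N} are excluded: they contribute to no
#' column, so column totals can fall below the subsequence count.
#'
#' @param subsequences character vector, all of length \code{h}.
#' @param h motif width; defaults to the common subsequence length.
#' @param detector identifier stored with the PFM.
#' @return a \linkS4class{MotifPFM}.
#' @export
buildPFM <- function(subsequences, h = NULL, detector = "detector") {
  if (length(subsequences) == 0L) {
    if (is.null(h)) stop("h must be given for an empty subsequence list")
  } else {
    lens <- unique(nchar(subsequences))
    if (length(lens) != 1L) stop("all subsequences must have the same length")
    if (is.null(h)) h <- lens
    if (lens != h) stop("subsequence length does not match h")
  }
  counts <- matrix(0L, nrow = 4L, ncol = h,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in subsequences) {
    chars <- .seqChars(s)
    for (j in seq_len(h)) {
      b <- chars[j]
      if (b != "N") counts[b, j] <- counts[b, j] + 1L
    }
  }
  new("MotifPFM", detector = as.character(detector), counts = counts,
      nSubseq = length(subsequences), nonN = as.integer(colSums(counts)))
}

#' Detector PFMs from positive fragments
#'
#' Convenience wrapper: extracts subsequences per detector and builds
#' one PFM per detector passing the minimum-contribution filter.
#'
#' @param model a trained \linkS4class{CapsModel}.
#' @param positives positive fragments (see
#'   \code{\link{extractSubsequences}}).
#' @param minSubseq minimum contributing subsequences per detector
#'   (default 10).
#' @return named list of \linkS4class{MotifPFM}.
#' @export
detectorPFMs <- function(model, positives, minSubseq = 10L) {
  subs <- extractSubsequences(model, positives)
  keep <- which(lengths(subs) >= minSubseq)
  out <- lapply(keep, function(k)
    buildPFM(subs[[k]], h = model@config$h,
             detector = sprintf("detector_%d", k)))
  names(out) <- sprintf("detector_%d", keep)
  out
}

#' @rdname pfmCounts
#' @export
setMethod("pfmCounts", "MotifPFM", function(x) x@counts)

setMethod("show", "MotifPFM", function(object) {
  cat(sprintf("MotifPFM '%s': width %d, %d contributing subsequences\n",
              object@detector, ncol(object@counts), object@nSubseq))
  cat("  consensus:", pfmConsensus(object), "\n")
})

#' PFM probabilities
#'
#' Converts counts to per-column probabilities with a pseudocount
#' (default 0.25 per cell); all-N columns become uniform.
#'
#' @param pfm a \linkS4class{MotifPFM}.
#' @param pseudocount per-cell pseudocount.
#' @return numeric 4 x h matrix, columns summing to 1.
#' @export
pfmProbabilities <- function(pfm, pseudocount = 0.25) {
  cnt <- pfm@counts + pseudocount
  sweep(cnt, 2L, colSums(cnt), "/")
}

#' Consensus sequence of a PFM
#'
#' Most frequent base per column (first on ties); all-N columns give
#' \code{N}.
#'
#' @param pfm a \linkS4class{MotifPFM}.
#' @param rna render with U instead of T.
#' @export
pfmConsensus <- function(pfm, rna = FALSE) {
  bases <- rownames(pfm@counts)
  cons <- vapply(seq_len(ncol(pfm@counts)), function(j) {
    if (pfm@nonN[j] == 0L) return("N")
    bases[which.max(pfm@counts[, j])]
  }, character(1))
  out <- paste(cons, collapse = "")
  if (rna) chartr("T", "U", out) else out
}

#' Per-column information content
#'
#' \eqn{IC_j = 2 + \sum_b p_b \log_2 p_b} bits (with 0 log 0 = 0),
#' computed from the raw count frequencies.  All-N columns score 0 and
#' are flagged.
#'
#' @param pfm a \linkS4class{MotifPFM}.
#' @return list with \code{ic} (bits per column), \code{total},
#'   \code{heights} (4 x h letter heights p_b * IC for logo drawing) and
#'   \code{allN} flags.
#' @export
informationContent <- function(pfm) {
  h <- ncol(pfm@counts)
  ic <- numeric(h)
  heights <- matrix(0, nrow = 4L, ncol = h,
                    dimnames = list(rownames(pfm@counts), NULL))
  allN <- pfm@nonN == 0L
  for (j in seq_len(h)) {
    if (allN[j]) next
    p <- pfm@counts[, j] / pfm@nonN[j]
    plogp <- ifelse(p > 0, p * log2(p), 0)
    ic[j] <- 2 + sum(plogp)
    heights[, j] <- p * ic[j]
  }
  list(ic = ic, total = sum(ic), heights = heights, allN = allN)
}

#' Export motifs in MEME minimal format
#'
#' Writes the PFMs as letter-probability matrices in MEME minimal
#' format, suitable for downstream motif-comparison tools (e.g. Tomtom
#' alignment against a reference motif collection).  Zero-count columns
#' emit uniform probabilities; empty PFMs are skipped with a warning.
#'
#' @param pfms list of \linkS4class{MotifPFM}.
#' @param path output file path.
#' @param background length-4 base frequencies (A, C, G, T/U), summing
#'   to 1.
#' @param alphabet \code{"RNA"} (letters ACGU, the display convention
#'   for RNA motifs) or \code{"DNA"}.
#' @param pseudocount passed to \code{\link{pfmProbabilities}}.
#' @return the path, invisibly.
#' @export
exportMEME <- function(pfms, path, background = rep(0.25, 4),
                       alphabet = c("RNA", "DNA"), pseudocount = 0.25) {
  alphabet <- match.arg(alphabet)
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  if (is(pfms, "MotifPFM")) pfms <- list(pfms)
  if (length(pfms) == 0L) stop("no PFMs to export")
  letters <- if (alphabet == "RNA") c("A", "C", "G", "U") else c("A", "C", "G", "T")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(letters, collapse = "")), "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", letters, background), collapse = " "),
               ""), con)
  for (i in seq_along(pfms)) {
    pfm <- pfms[[i]]
    if (pfm@nSubseq == 0L) {
      warning(sprintf("skipping empty PFM '%s'", pfm@detector))
      next
    }
    pr <- pfmProbabilities(pfm, pseudocount)
    writeLines(sprintf("MOTIF %s", pfm@detector), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(pr), pfm@nSubseq), con)
    for (j in seq_len(ncol(pr)))
      writeLines(paste(sprintf("%.6f", pr[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Parse a MEME minimal-format file
#'
#' Reads back motifs written by \code{\link{exportMEME}} (or any MEME
#' minimal file with letter-probability matrices).
#'
#' @param path MEME file path.
#' @return list with \code{alphabet}, \code{background}, and
#'   \code{motifs}: named list of 4 x w probability matrices.
#' @export
readMEME <- function(path) {
  lines <- readLines(path)
  alpha <- sub("^ALPHABET= *", "", grep("^ALPHABET=", lines, value = TRUE)[1])
  bgi <- grep("^Background letter frequencies", lines)
  background <- NULL
  if (length(bgi)) {
    toks <- strsplit(trimws(lines[bgi[1] + 1L]), "\\s+")[[1]]
    background <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(background) <- toks[seq(1, length(toks), by = 2)]
  }
  starts <- grep("^MOTIF ", lines)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(trimws(sub("^MOTIF ", "", lines[s])), "\\s+")[[1]][1]
    hdr <- s + 1L
    while (hdr <= length(lines) && !grepl("^letter-probability matrix", lines[hdr]))
      hdr <- hdr + 1L
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    mat <- t(m)
    rownames(mat) <- strsplit(alpha, "")[[1]]
    motifs[[name]] <- mat
  }
  list(alphabet = alpha, background = background, motifs = motifs)
}

#' Draw a sequence logo
#'
#' Minimal stacked-letter logo from a PFM's information content: per
#' column, letters are stacked in increasing frequency order with total
#' height equal to the column's information content (bits).  Rendered
#' with base graphics; RNA display uses U.
#'
#' @param pfm a \linkS4class{MotifPFM}.
#' @param rna draw U instead of T (default TRUE: motif logos for RNA).
#' @param main plot title.
#' @export
plotLogo <- function(pfm, rna = TRUE, main = pfm@detector) {
  ic <- informationContent(pfm)
  h <- ncol(pfm@counts)
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  graphics::plot(NA, xlim = c(0.5, h + 0.5), ylim = c(0, 2),
                 xlab = "position", ylab = "bits", main = main,
                 xaxs = "i", yaxs = "i", las = 1)
  for (j in seq_len(h)) {
    hts <- ic$heights[, j]
    ord <- order(hts)
    y <- 0
    for (b in rownames(ic$heights)[ord]) {
      hb <- ic$heights[b, j]
      if (hb < 1e-3) next
      lab <- if (rna && b == "T") "U" else b
      cex <- max(0.2, min(4, hb * 2.2))
      graphics::text(j, y + hb / 2, lab, col = cols[[b]], cex = cex, font = 2)
      y <- y + hb
    }
  }
  invisible(ic)
}
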