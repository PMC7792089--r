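#' Scan a full-length circular RNA for binding sites
#'
#' Slides a window of the model's fragment length over the sequence and
#' scores every window with the trained classifier.  In circular mode
#' (the default) the first W-1 nucleotides are appended so windows
#' crossing the back-splice junction are covered; a circRNA has no free
#' ends, so junction-spanning sites are legitimate candidates.  Hits are
#' ranked by score (descending), ties broken by start position.
#'
#' Coordinates are 1-based inclusive on the input sequence.  A wrapped
#' window keeps its start on the original sequence, sets
#' \code{wrapped = TRUE} and reports the wrapped (modulo-length) end
#' rather than an end beyond the sequence.
#'
#' @param sequence a nucleotide string (or length-1 \code{DNAStringSet}).
#' @param model a trained \linkS4class{CapsModel}; its fragment length is
#'   the window width W.
#' @param stride window step in nt (default 1).
#' @param circular scan across the back-splice junction (default TRUE).
#' @param scoreFun optional scorer overriding the model: a function
#'   mapping a character vector of windows to numeric scores (used for
#'   testing the window machinery).
#' @return data frame of ranked hits: \code{start}, \code{end},
#'   \code{wrapped}, \code{score}; the sequence length is attached as
#'   attribute \code{seqLength} and the window width as \code{window}.
#' @export
scanCircRNA <- function(sequence, model, stride = 1L, circular = TRUE,
                        scoreFun = NULL) {
  if (is(sequence, "XStringSet")) {
    stopifnot(length(sequence) == 1L)
    sequence <- as.character(sequence[[1L]])
  }
  sequence <- gsub("U", "T", toupper(as.character(sequence)), fixed = TRUE)
  W <- if (is.null(scoreFun)) model@config$L else attr(scoreFun, "window")
  if (is.null(W)) W <- model@config$L
  Lseq <- nchar(sequence)
  if (!circular && Lseq < W)
    stop("sequence is shorter than the window; use circular = TRUE")
  # circular windows may wrap (for Lseq < W, more than once)
  ext <- if (circular) {
    reps <- ceiling((Lseq + W - 1L) / Lseq)
    substr(strrep(sequence, reps), 1L, Lseq + W - 1L)
  } else sequence
  starts <- if (circular) seq.int(1L, Lseq, by = stride)
            else seq.int(1L, Lseq - W + 1L, by = stride)
  windows <- substring(ext, starts, starts + W - 1L)
  scores <- if (!is.null(scoreFun)) {
    as.numeric(scoreFun(windows))
  } else {
    predictScores(model, windows)[, "scorePos"]
  }
  endRaw <- starts + W - 1L
  wrapped <- endRaw > Lseq
  ends <- ifelse(wrapped, endRaw - Lseq, endRaw)
  hits <- data.frame(start = starts, end = as.integer(ends),
                     wrapped = wrapped, score = scores)
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "seqLength") <- Lseq
  attr(hits, "window") <- W
  hits
}

# positions (1-based, on the circle) covered by a hit
.hitPositions <- function(start, W, Lseq) {
  ((start - 1L + seq_len(W) - 1L) %% Lseq) + 1L
}

#' Top non-overlapping scan hits
#'
#' Greedy selection by score: the highest-scoring hit is taken first and
#' hits overlapping an already-selected hit (on the circle) are skipped,
#' until k hits are reported.  Equal-score overlapping hits resolve to
#' the earlier start.
#'
#' @param hits a ranked hit table from \code{\link{scanCircRNA}}.
#' @param k number of hits to report (default 1).
#' @return data frame of at most k hits.
#' @export
reportTopHits <- function(hits, k = 1L) {
  if (k < 1L) stop("k must be >= 1")
  if (nrow(hits) == 0L) stop("empty hit list")
  Lseq <- attr(hits, "seqLength")
  W <- attr(hits, "window")
  covered <- logical(Lseq)
  sel <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (length(sel) >= k) break
    pos <- .hitPositions(hits$start[i], W, Lseq)
    if (any(covered[pos])) next
    covered[pos] <- TRUE
    sel <- c(sel, i)
  }
  out <- hits[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seqLength") <- Lseq
  attr(out, "window") <- W
  out
}

#' Scan a FASTA of circRNAs and write a hit table
#'
#' Runs \code{\link{scanCircRNA}} on every record and writes a
#' tab-delimited table (id, start, end, wrapped, score) of the top k
#' non-overlapping hits per sequence.
#'
#' @param fasta path to a FASTA of full-length circRNA sequences.
#' @param model a trained \linkS4class{CapsModel}.
#' @param path output TSV path.
#' @param k top hits per sequence (default 1).
#' @param stride,circular passed to \code{\link{scanCircRNA}}.
#' @return the hit table, invisibly.
#' @export
scanFastaToTSV <- function(fasta, model, path, k = 1L, stride = 1L,
                           circular = TRUE) {
  seqs <- readFastaSites(fasta)
  out <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    hits <- scanCircRNA(as.character(seqs[[i]]), model, stride = stride,
                        circular = circular)
    top <- reportTopHits(hits, k = k)
    cbind(id = names(seqs)[i], top)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write scan hits as BED
#'
#' Converts 1-based inclusive hit coordinates to BED's 0-based
#' half-open convention.  A wrapped hit is split into its two arcs
#' (junction-crossing windows occupy the sequence end and start).
#'
#' @param hits hit table with an \code{id} column (or a single-sequence
#'   table from \code{\link{scanCircRNA}}).
#' @param path output BED path.
#' @param id sequence name used when \code{hits} has no id column.
#' @export
writeHitsBED <- function(hits, path, id = "circRNA") {
  Lseq <- attr(hits, "seqLength")
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    nm <- if ("id" %in% names(hits)) hits$id[i] else id
    sc <- hits$score[i]
    if (isTRUE(hits$wrapped[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = nm, start = hits$start[i] - 1L, end = Lseq,
        name = sprintf("hit_%d_a", i), score = sc)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = nm, start = 0L, end = hits$end[i],
        name = sprintf("hit_%d_b", i), score = sc)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = nm, start = hits$start[i] - 1L, end = hits$end[i],
        name = sprintf("hit_%d", i), score = sc)
    }
  }
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
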