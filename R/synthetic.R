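#' Configuration for planted-motif simulations
#'
#' Describes the synthetic study conditions: background fragments of a
#' fixed length with one motif instance planted per positive at a
#' uniformly random offset, and negatives obtained by dinucleotide
#' shuffling the positives — the same construction used for real
#' binding-site datasets.  The default motif ACTAAC is the DNA form of
#' the canonical QKI binding motif (ACUAAC).
#'
#' @param nPos number of positive fragments.
#' @param L fragment length in nt (default 50).
#' @param motif consensus string, or a 4 x w probability matrix (rows A,
#'   C, G, T) sampled per column.
#' @param plantProb probability a positive receives a motif instance
#'   (default 1).
#' @param background length-4 base sampling frequencies (A, C, G, T),
#'   summing to 1; default uniform.  A GC-rich background (e.g.
#'   \code{c(0.15, 0.35, 0.35, 0.15)}) checks that shuffled negatives —
#'   not raw base composition — carry the classification difficulty.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of it.
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(nPos = 2000L, L = 50L, motif = "ACTAAC",
                      plantProb = 1.0, background = rep(0.25, 4),
                      seed = 1L) {
  if (abs(sum(background) - 1) > 1e-8)
    stop("background frequencies must sum to 1")
  w <- if (is.character(motif)) nchar(motif) else ncol(motif)
  if (w > L) stop("motif is longer than the fragment length")
  if (is.matrix(motif)) {
    if (nrow(motif) != 4L) stop("a motif matrix must have 4 rows (A, C, G, T)")
    if (any(abs(colSums(motif) - 1) > 1e-8))
      stop("motif matrix columns must sum to 1")
  }
  structure(list(nPos = as.integer(nPos), L = as.integer(L), motif = motif,
                 plantProb = plantProb, background = background,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

.BASES <- c("A", "C", "G", "T")

.sampleBackground <- function(L, background) {
  paste(sample(.BASES, L, replace = TRUE, prob = background), collapse = "")
}

.sampleMotifInstance <- function(motif) {
  if (is.character(motif)) return(toupper(motif))
  paste(vapply(seq_len(ncol(motif)), function(j)
    sample(.BASES, 1L, prob = motif[, j]), character(1)), collapse = "")
}

#' Simulate a planted-motif binding-site dataset
#'
#' Positives are background fragments with (at most) one planted motif
#' instance at a uniformly random valid offset; negatives are
#' dinucleotide-preserving shuffles of the positives, so the negative
#' pool's 16 dinucleotide counts equal the positive pool's exactly.
#' Fully determined by the config seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{sites} (a \linkS4class{BindingSiteSet}) and
#'   \code{truth}: a data frame of planted positions (id, start, end;
#'   NA when no instance was planted).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  w <- if (is.character(cfg$motif)) nchar(cfg$motif) else ncol(cfg$motif)
  withr::with_seed(cfg$seed, {
    pos <- character(cfg$nPos)
    starts <- rep(NA_integer_, cfg$nPos)
    for (i in seq_len(cfg$nPos)) {
      s <- .sampleBackground(cfg$L, cfg$background)
      if (stats::runif(1) <= cfg$plantProb) {
        st <- sample.int(cfg$L - w + 1L, 1L)
        inst <- .sampleMotifInstance(cfg$motif)
        s <- paste0(substr(s, 1L, st - 1L), inst, substr(s, st + w, cfg$L))
        starts[i] <- st
      }
      pos[i] <- s
    }
    neg <- vapply(pos, .dinucShuffle, character(1), USE.NAMES = FALSE)
  })
  ids <- sprintf("pos_%04d", seq_len(cfg$nPos))
  negIds <- sprintf("neg_%04d", seq_len(cfg$nPos))
  sites <- new("BindingSiteSet",
               sequences = Biostrings::DNAStringSet(
                 stats::setNames(c(pos, neg), c(ids, negIds))),
               label = factor(rep(c("positive", "negative"), each = cfg$nPos),
                              levels = c("positive", "negative")),
               source = rep(c("synthetic", "shuffled"), each = cfg$nPos),
               pairedWith = c(rep(NA_character_, cfg$nPos), ids),
               policy = lengthPolicy(cfg$L))
  truth <- data.frame(id = ids, start = starts,
                      end = ifelse(is.na(starts), NA_integer_,
                                   starts + w - 1L))
  list(sites = sites, truth = truth)
}

#' Simulate full-length circular RNAs with planted sites
#'
#' Generates circular background sequences with \code{nSites}
#' non-overlapping planted motif occurrences at recorded positions;
#' placements may wrap across the back-splice junction.  Intended as an
#' end-to-end fixture for window scanning.
#'
#' @param cfg a \code{\link{simConfig}} (motif, background and seed are
#'   used).
#' @param Lcirc circRNA length in nt.
#' @param nSites planted occurrences per sequence.
#' @param nSeqs number of circRNA sequences (default 1).
#' @return list with \code{sequences} (named \code{DNAStringSet}) and
#'   \code{truth}: data frame (id, start, end, wrapped), 1-based
#'   inclusive, wrapped ends reported modulo the length.
#' @export
simulateFullCircRNA <- function(cfg, Lcirc, nSites = 1L, nSeqs = 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  w <- if (is.character(cfg$motif)) nchar(cfg$motif) else ncol(cfg$motif)
  if (nSites * w > Lcirc)
    stop("placement overcrowded: nSites * motif width exceeds the sequence length")
  res <- withr::with_seed(cfg$seed, {
    seqs <- character(nSeqs)
    truth <- list()
    for (i in seq_len(nSeqs)) {
      chars <- strsplit(.sampleBackground(Lcirc, cfg$background), "")[[1]]
      occupied <- logical(Lcirc)
      placed <- 0L
      tries <- 0L
      while (placed < nSites) {
        tries <- tries + 1L
        if (tries > 1000L * nSites)
          stop("placement overcrowded: could not plant all sites")
        st <- sample.int(Lcirc, 1L)
        posIdx <- ((st - 1L + seq_len(w) - 1L) %% Lcirc) + 1L
        if (any(occupied[posIdx])) next
        inst <- strsplit(.sampleMotifInstance(cfg$motif), "")[[1]]
        chars[posIdx] <- inst
        occupied[posIdx] <- TRUE
        placed <- placed + 1L
        endRaw <- st + w - 1L
        truth[[length(truth) + 1L]] <- data.frame(
          id = sprintf("circ_%03d", i), start = st,
          end = if (endRaw > Lcirc) endRaw - Lcirc else endRaw,
          wrapped = endRaw > Lcirc)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    list(seqs = seqs, truth = truth)
  })
  list(sequences = Biostrings::DNAStringSet(
         stats::setNames(res$seqs, sprintf("circ_%03d", seq_len(nSeqs)))),
       truth = do.call(rbind, res$truth))
}

#' Write a truth table as BED
#'
#' 0-based half-open conversion of planted-site coordinates; wrapped
#' sites are split into their two arcs.
#'
#' @param truth truth data frame from \code{\link{simulateFullCircRNA}}.
#' @param Lcirc circRNA length.
#' @param path output BED path.
#' @export
writeTruthBED <- function(truth, Lcirc, path) {
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    if (isTRUE(truth$wrapped[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = truth$id[i], start = truth$start[i] - 1L, end = Lcirc,
        name = sprintf("site_%d_a", i))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = truth$id[i], start = 0L, end = truth$end[i],
        name = sprintf("site_%d_b", i))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = truth$id[i], start = truth$start[i] - 1L,
        end = truth$end[i], name = sprintf("site_%d", i))
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
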