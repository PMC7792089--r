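#' Dinucleotide-preserving shuffle
#'
#' Permutes a sequence so that all 16 dinucleotide (adjacent-pair) counts
#' are exactly preserved, via an Euler-path construction on the base
#' transition multigraph (Altschul--Erikson style): each shuffle is a new
#' Eulerian path through the same edge multiset, so the first and last
#' characters are also preserved.  Shuffled negatives built this way stop
#' a classifier from separating foreground and background on low-order
#' composition alone.
#'
#' If the randomised path reproduces the input, the construction is
#' retried (up to 10 times) before the identical permutation is accepted;
#' low-complexity sequences can admit a unique Eulerian path.
#'
#' @param s nucleotide string over A, C, G, T (length >= 2, no N).
#' @param seed optional integer seed; when supplied the shuffle is run in
#'   an isolated RNG scope and is reproducible, otherwise the current RNG
#'   stream is used.
#' @return a shuffled string with identical dinucleotide counts and
#'   identical first/last characters.
#' @examples
#' dinucleotideShuffle("ACGTACGTAC", seed = 1)
#' @export
dinucleotideShuffle <- function(s, seed = NULL) {
  if (is.null(seed)) return(.dinucShuffle(s))
  withr::with_seed(as.integer(seed), .dinucShuffle(s))
}

.dinucShuffle <- function(s) {
  chars <- .seqChars(s)
  if (length(chars) < 2L)
    stop("sequence must have length >= 2 to be dinucleotide-shuffled")
  if (any(chars == "N"))
    stop("dinucleotide shuffle operates on the raw site: no N allowed")
  for (attempt in seq_len(10L)) {
    out <- .eulerShuffleOnce(chars)
    if (!identical(out, chars)) break
  }
  paste(out, collapse = "")
}

# One randomised Eulerian path through the dinucleotide multigraph.
.eulerShuffleOnce <- function(chars) {
  L <- length(chars)
  verts <- unique(chars)
  first <- chars[1L]
  last <- chars[L]
  out <- split(chars[-1L], factor(chars[-L], levels = verts))

  # pick a random "last exit" edge per non-terminal vertex such that the
  # chosen edges form paths leading to the terminal vertex
  nonTerm <- setdiff(names(out)[lengths(out) > 0L], last)
  repeat {
    lastEdge <- vapply(nonTerm, function(v) {
      o <- out[[v]]
      o[sample.int(length(o), 1L)]
    }, character(1))
    if (.reachesTerminal(lastEdge, nonTerm, last)) break
  }

  # order each vertex's exits: random permutation, chosen last exit last
  ordered <- stats::setNames(vector("list", length(verts)), verts)
  for (v in verts) {
    o <- out[[v]]
    if (length(o) == 0L) { ordered[[v]] <- character(0); next }
    if (v %in% nonTerm) {
      drop1 <- match(lastEdge[[v]], o)
      rest <- o[-drop1]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      ordered[[v]] <- c(rest, lastEdge[[v]])
    } else {
      ordered[[v]] <- if (length(o) > 1L) o[sample.int(length(o))] else o
    }
  }

  # walk the Eulerian path
  res <- character(L)
  res[1L] <- first
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  cur <- first
  for (i in 2L:L) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  res
}

# do the chosen last-exit edges lead every non-terminal vertex to `last`?
.reachesTerminal <- function(lastEdge, nonTerm, last) {
  for (v in nonTerm) {
    cur <- v
    steps <- 0L
    while (cur != last) {
      if (!cur %in% nonTerm) return(FALSE)   # dead end before terminal
      cur <- lastEdge[[cur]]
      steps <- steps + 1L
      if (steps > length(nonTerm) + 1L) return(FALSE)  # cycle
    }
  }
  TRUE
}

#' Dinucleotide count vector
#'
#' Counts of all 16 adjacent base pairs, in AA, AC, ..., TT order.
#'
#' @param s nucleotide string (A, C, G, T).
#' @return named integer vector of length 16.
#' @export
dinucleotideCounts <- function(s) {
  chars <- .seqChars(s)
  bases <- c("A", "C", "G", "T")
  lv <- as.vector(outer(bases, bases, function(a, b) paste0(a, b)))
  lv <- sort(lv)
  di <- paste0(chars[-length(chars)], chars[-1L])
  table(factor(di, levels = lv))
}
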