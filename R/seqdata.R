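#' One-hot encode a nucleotide sequence
#'
#' Encodes a fragment as an L x 4 binary matrix with columns in A, T, C, G
#' order; \code{N} encodes as an all-zero row.  \code{U} is normalised to
#' \code{T} on input, and lower case is accepted.
#'
#' @param s a single nucleotide string over A, C, G, T, U, N.
#' @return integer matrix \code{L x 4} with column names A, T, C, G.
#' @examples
#' encodeSequence("NGACAN")
#' @export
encodeSequence <- function(s) {
  chars <- .seqChars(s)
  M <- matrix(0L, nrow = length(chars), ncol = 4L,
              dimnames = list(NULL, .ALPHABET))
  for (j in seq_along(.ALPHABET))
    M[chars == .ALPHABET[j], j] <- 1L
  M
}

#' Decode a one-hot matrix back to its sequence
#'
#' Inverse of \code{\link{encodeSequence}}: all-zero rows decode to
#' \code{N}.
#'
#' @param M an L x 4 one-hot matrix (columns A, T, C, G).
#' @return a nucleotide string.
#' @export
decodeSequence <- function(M) {
  stopifnot(is.matrix(M), ncol(M) == 4L)
  rs <- rowSums(M != 0)
  if (any(rs > 1L))
    stop("matrix is not one-hot: some rows have more than one non-zero entry")
  idx <- max.col(M, ties.method = "first")
  out <- .ALPHABET[idx]
  out[rs == 0L] <- "N"
  paste(out, collapse = "")
}

# split, upper-case, U->T, validate; reports the first offending position
.seqChars <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L)
    stop("sequence must be a single non-empty string")
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  chars[chars == "U"] <- "T"
  bad <- which(!chars %in% c(.ALPHABET, "N"))
  if (length(bad))
    stop(sprintf("unknown character '%s' at position %d", chars[bad[1L]], bad[1L]))
  chars
}

# integer codes for the C++ core: 0=A 1=T 2=C 3=G 4=N
.seqCodes <- function(s) {
  chars <- .seqChars(s)
  match(chars, c(.ALPHABET, "N")) - 1L
}

# codes matrix (one row per sequence); all sequences must share a length
.codesMatrix <- function(seqs) {
  seqs <- as.character(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("all sequences must have the same length for batch encoding")
  do.call(rbind, lapply(seqs, .seqCodes))
}

#' Boxplot length threshold
#'
#' Tukey upper fence Q3 + 1.5 IQR of the site-length distribution, with
#' quartiles by linear interpolation (type-7 quantiles), rounded half-up
#' to the nearest integer.  Sites longer than the returned threshold are
#' treated as length outliers and discarded.
#'
#' @param lengths integer vector of binding-site lengths.
#' @return integer threshold length.
#' @export
lengthThreshold <- function(lengths) {
  if (length(lengths) == 0L || any(is.na(lengths)))
    stop("lengths must be a non-empty vector without NA")
  q <- stats::quantile(lengths, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2L] + 1.5 * (q[2L] - q[1L])
  as.integer(floor(fence + 0.5))
}

#' Centre-pad a fragment or signal a discard
#'
#' Fragments shorter than the policy threshold are centred and padded
#' with \code{N} to exactly the threshold length (an odd remainder goes
#' to the 3' side); fragments longer than the threshold return
#' \code{NULL}, the discard signal.
#'
#' @param s a nucleotide string.
#' @param policy a \linkS4class{LengthPolicy}.
#' @return the padded string, or \code{NULL} for a discarded fragment.
#' @export
padOrDiscard <- function(s, policy) {
  stopifnot(is(policy, "LengthPolicy"))
  L <- nchar(s)
  thr <- policy@thresholdL
  if (L > thr) return(NULL)
  extra <- thr - L
  left <- extra %/% 2L
  right <- extra - left
  paste0(strrep(policy@padChar, left), s, strrep(policy@padChar, right))
}

#' Build a balanced binding-site dataset
#'
#' From a FASTA file (or \code{DNAStringSet}) of observed positive
#' binding-site fragments: removes exact duplicate sequences, determines
#' (or applies) the boxplot length threshold, discards length outliers,
#' and generates one dinucleotide-preserving shuffled negative per kept
#' positive so the dataset is balanced by construction.  Deterministic
#' under \code{seed}.
#'
#' @param positives path to a FASTA file, or a named \code{DNAStringSet} /
#'   character vector of positive fragments.
#' @param policy optional \linkS4class{LengthPolicy}; when \code{NULL} the
#'   threshold is computed from the deduplicated site lengths with
#'   \code{\link{lengthThreshold}}.
#' @param seed integer seed for the shuffle randomisation.
#' @param ranges optional \link[IRanges]{IRanges} of site coordinates
#'   (parallel to \code{positives}); when supplied, sites whose Jaccard
#'   coordinate overlap with an already-kept site exceeds
#'   \code{maxJaccard} are dropped as redundant.
#' @param maxJaccard Jaccard overlap cutoff for the optional coordinate
#'   filter.
#' @return a \linkS4class{BindingSiteSet} with equal numbers of positive
#'   and negative records.
#' @export
buildDataset <- function(positives, policy = NULL, seed = 1L,
                         ranges = NULL, maxJaccard = 0.8) {
  seqs <- .asSiteStrings(positives)
  if (length(seqs) == 0L) stop("no positive sequences supplied")
  if (!is.null(ranges)) {
    keep <- .jaccardKeep(ranges, maxJaccard)
    seqs <- seqs[keep]
  }
  seqs <- seqs[!duplicated(as.character(seqs))]
  if (is.null(policy))
    policy <- lengthPolicy(lengthThreshold(nchar(as.character(seqs))))
  keep <- nchar(as.character(seqs)) <= policy@thresholdL
  seqs <- seqs[keep]
  if (length(seqs) == 0L) stop("no positive sequences survive length thresholding")
  posChar <- as.character(seqs)
  negChar <- withr::with_seed(seed, vapply(posChar, .dinucShuffle, character(1)))
  ids <- names(seqs)
  negIds <- paste0(ids, "_shuf")
  new("BindingSiteSet",
      sequences = Biostrings::DNAStringSet(
        stats::setNames(c(posChar, negChar), c(ids, negIds))),
      label = factor(rep(c("positive", "negative"), each = length(ids)),
                     levels = c("positive", "negative")),
      source = rep(c("observed", "shuffled"), each = length(ids)),
      pairedWith = c(rep(NA_character_, length(ids)), ids),
      policy = policy)
}

# accept path / DNAStringSet / character; normalise U->T and upper case
.asSiteStrings <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- readFastaSites(x)
  if (is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("positives must be a FASTA path, DNAStringSet or character vector")
  x <- chartr("u", "U", x)
  x <- gsub("U", "T", toupper(x), fixed = TRUE)
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- paste0("site_", seq_along(x))
  Biostrings::DNAStringSet(x)
}

# greedy redundancy filter: drop a site whose Jaccard overlap with any
# already-kept site exceeds the cutoff
.jaccardKeep <- function(ranges, maxJaccard) {
  n <- length(ranges)
  keep <- logical(n)
  kept <- IRanges::IRanges()
  for (i in seq_len(n)) {
    r <- ranges[i]
    if (length(kept) == 0L) {
      keep[i] <- TRUE; kept <- c(kept, r); next
    }
    pairs <- IRanges::findOverlapPairs(r, kept)
    if (length(pairs) == 0L) jac <- 0 else {
      inter <- IRanges::width(IRanges::pintersect(pairs))
      uni <- IRanges::width(S4Vectors::first(pairs)) +
        IRanges::width(S4Vectors::second(pairs)) - inter
      jac <- max(inter / uni)
    }
    if (jac <= maxJaccard) { keep[i] <- TRUE; kept <- c(kept, r) }
  }
  keep
}

#' Read binding-site fragments from FASTA
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file, upper-cases,
#' and normalises RNA \code{U} to \code{T}.
#'
#' @param path FASTA file path.
#' @return a named \code{DNAStringSet}.
#' @export
readFastaSites <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ch <- gsub("U", "T", toupper(as.character(x)), fixed = TRUE)
  names(ch) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(ch)
}

#' Write sequences to FASTA
#'
#' @param seqs named \code{DNAStringSet} or character vector.
#' @param path output file path.
#' @export
writeFastaSites <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Write a dataset manifest
#'
#' Tab-delimited table of record id, label, raw length and provenance.
#'
#' @param x a \linkS4class{BindingSiteSet}.
#' @param path output TSV path.
#' @export
writeManifest <- function(x, path) {
  stopifnot(is(x, "BindingSiteSet"))
  df <- data.frame(id = names(x@sequences),
                   label = as.character(x@label),
                   length = Biostrings::width(x@sequences),
                   source = x@source,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# pad all fragments to the policy length and return the codes matrix plus
# 0/1 labels (1 = positive), in record order
.encodeSet <- function(x) {
  stopifnot(is(x, "BindingSiteSet"))
  padded <- vapply(as.character(x@sequences), padOrDiscard, character(1),
                   policy = x@policy)
  list(codes = .codesMatrix(padded),
       labels = as.integer(x@label == "positive"),
       padded = unname(padded))
}

#' @rdname siteSequences
#' @export
setMethod("siteSequences", "BindingSiteSet", function(x) x@sequences)

#' @rdname siteLabels
#' @export
setMethod("siteLabels", "BindingSiteSet", function(x) x@label)

#' @rdname siteSources
#' @export
setMethod("siteSources", "BindingSiteSet", function(x) x@source)

#' @rdname sitePolicy
#' @export
setMethod("sitePolicy", "BindingSiteSet", function(x) x@policy)

setMethod("show", "BindingSiteSet", function(object) {
  tab <- table(object@label)
  cat("BindingSiteSet with", length(object@sequences), "records (",
      tab[["positive"]], "positive /", tab[["negative"]], "negative )\n")
  cat("  fragment length threshold:", object@policy@thresholdL, "nt\n")
  cat("  sources:", paste(unique(object@source), collapse = ", "), "\n")
})

#' Subset a binding-site set
#' @param x a \linkS4class{BindingSiteSet}.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "BindingSiteSet", function(x, i, j, ..., drop = FALSE) {
  new("BindingSiteSet", sequences = x@sequences[i], label = x@label[i],
      source = x@source[i], pairedWith = x@pairedWith[i], policy = x@policy)
})

#' Number of records
#' @param x a \linkS4class{BindingSiteSet}.
#' @export
setMethod("length", "BindingSiteSet", function(x) length(x@sequences))
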