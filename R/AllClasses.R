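#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Biostrings DNAStringSet XStringSet
#' @importFrom stats quantile rnorm runif median setNames
#' @importFrom utils write.table
#' @useDynLib capsRBP, .registration = TRUE
NULL

#' One-hot alphabet column order
#'
#' Nucleotide order of the one-hot columns used throughout the package:
#' A, T, C, G. \code{N} (and only \code{N}) encodes as an all-zero row.
#' @keywords internal
.ALPHABET <- c("A", "T", "C", "G")

#' Length policy for binding-site fragments
#'
#' Fixes the fragment length every encoded binding site must have.  Sites
#' shorter than \code{thresholdL} are centred and padded with \code{N}
#' (odd remainder on the 3' side); longer sites are discarded as length
#' outliers.
#'
#' @slot thresholdL integer fragment length in nt (>= 1).
#' @slot padChar padding character, always \code{"N"}.
#' @export
setClass("LengthPolicy",
  representation(thresholdL = "integer", padChar = "character"),
  validity = function(object) {
    if (length(object@thresholdL) != 1L || is.na(object@thresholdL) ||
        object@thresholdL < 1L)
      return("thresholdL must be a single integer >= 1")
    if (!identical(object@padChar, "N"))
      return("padChar must be 'N'")
    TRUE
  })

#' @param thresholdL integer fragment length in nt.
#' @rdname LengthPolicy-class
#' @export
lengthPolicy <- function(thresholdL) {
  new("LengthPolicy", thresholdL = as.integer(thresholdL), padChar = "N")
}

#' Paired positive/negative binding-site collection
#'
#' Holds raw (unpadded) binding-site fragments together with their labels
#' and provenance.  Negative records are dinucleotide-preserving shuffles
#' of positives and carry the id of the positive they were shuffled from.
#'
#' @slot sequences a \link[Biostrings]{DNAStringSet} of raw fragments.
#' @slot label factor with levels \code{positive}, \code{negative}.
#' @slot source character: \code{observed}, \code{shuffled} or
#'   \code{synthetic}.
#' @slot pairedWith character: for negatives, the id of the source
#'   positive; \code{NA} otherwise.
#' @slot policy the \linkS4class{LengthPolicy} all fragments obey.
#' @export
setClass("BindingSiteSet",
  representation(sequences = "DNAStringSet", label = "factor",
                 source = "character", pairedWith = "character",
                 policy = "LengthPolicy"),
  validity = function(object) {
    n <- length(object@sequences)
    if (length(object@label) != n || length(object@source) != n ||
        length(object@pairedWith) != n)
      return("sequences, label, source and pairedWith must have equal length")
    if (!identical(levels(object@label), c("positive", "negative")))
      return("label must be a factor with levels positive, negative")
    if (!all(object@source %in% c("observed", "shuffled", "synthetic")))
      return("source must be one of observed, shuffled, synthetic")
    neg <- object@label == "negative"
    if (any(neg & is.na(object@pairedWith)))
      return("negative records must carry the id of their source positive")
    if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
      return("sequences must have unique names")
    if (any(Biostrings::width(object@sequences) > object@policy@thresholdL))
      return("all fragments must be at most thresholdL long")
    TRUE
  })

#' Capsule-network model
#'
#' All trainable state of the classifier: convolutional motif detectors
#' (weights \code{h x 4 x K} and biases), per-(input, output) capsule
#' affine matrices, and the architecture/loss configuration.
#'
#' @slot convW numeric array \code{h x 4 x K}: detector weights, columns
#'   in A,T,C,G order.
#' @slot convB numeric length-\code{K} detector biases.
#' @slot capsW numeric array \code{dOut x dIn x (n * 2)}: affine matrices
#'   \eqn{W^{ij}}, slices ordered class-major (all inputs of digit capsule
#'   1, then of digit capsule 2).
#' @slot config list of architecture constants: \code{L} (fragment
#'   length), \code{h}, \code{K}, \code{dIn}, \code{dOut}, \code{nClass},
#'   \code{T} (routing rounds), \code{maxpool}, margin-loss constants
#'   \code{mPlus}, \code{mMinus}, \code{lambda}, and \code{alphabet}.
#' @export
setClass("CapsModel",
  representation(convW = "array", convB = "numeric", capsW = "array",
                 config = "list"),
  validity = function(object) {
    cfg <- object@config
    need <- c("L", "h", "K", "dIn", "dOut", "nClass", "T", "maxpool",
              "mPlus", "mMinus", "lambda", "alphabet")
    if (!all(need %in% names(cfg)))
      return(paste("config must contain:", paste(need, collapse = ", ")))
    if (!identical(dim(object@convW), c(cfg$h, 4L, cfg$K)))
      return("convW must be h x 4 x K")
    if (length(object@convB) != cfg$K)
      return("convB must have length K")
    n <- .nPrimaryCaps(cfg)
    if (!identical(dim(object@capsW), c(cfg$dOut, cfg$dIn, n * cfg$nClass)))
      return("capsW must be dOut x dIn x (n * nClass)")
    if (!(cfg$mMinus > 0 && cfg$mMinus < cfg$mPlus && cfg$mPlus < 1))
      return("margin constants must satisfy 0 < mMinus < mPlus < 1")
    if (!identical(cfg$alphabet, .ALPHABET))
      return("alphabet must be A,T,C,G")
    TRUE
  })

.nPrimaryCaps <- function(cfg) {
  P <- cfg$L - cfg$h + 1L
  if (isTRUE(cfg$maxpool)) cfg$K %/% cfg$dIn else (cfg$K %/% cfg$dIn) * P
}

#' Cross-validation result
#'
#' @slot foldAssignments integer fold id per instance.
#' @slot foldAUC numeric per-fold AUC.
#' @slot rocCurves list of per-fold ROC point data frames (fpr, tpr).
#' @slot scores numeric held-out binding scores, in instance order.
#' @slot labels integer held-out labels (1 = positive), in instance order.
#' @export
setClass("CVResult",
  representation(foldAssignments = "integer", foldAUC = "numeric",
                 rocCurves = "list", scores = "numeric", labels = "integer"),
  validity = function(object) {
    if (length(object@scores) != length(object@labels) ||
        length(object@scores) != length(object@foldAssignments))
      return("scores, labels and foldAssignments must have equal length")
    if (any(object@foldAUC < 0 | object@foldAUC > 1))
      return("AUC values must lie in [0, 1]")
    TRUE
  })

#' Position frequency matrix for one motif detector
#'
#' Per-column base counts over the subsequences a convolution detector
#' selected from positive fragments.  \code{N} characters contribute to no
#' column, so each column's counts sum to its non-N total, which is at
#' most the number of contributing subsequences.
#'
#' @slot detector detector identifier.
#' @slot counts integer matrix \code{4 x h}, rows A, C, G, T.
#' @slot nSubseq number of contributing subsequences.
#' @slot nonN integer per-column non-N totals.
#' @export
setClass("MotifPFM",
  representation(detector = "character", counts = "matrix",
                 nSubseq = "integer", nonN = "integer"),
  validity = function(object) {
    if (!identical(rownames(object@counts), c("A", "C", "G", "T")))
      return("counts rows must be A, C, G, T")
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
      return("counts must be non-negative integers")
    if (length(object@nonN) != ncol(object@counts))
      return("nonN must have one entry per column")
    if (!all(colSums(object@counts) == object@nonN))
      return("column sums must equal the non-N totals")
    if (any(object@nonN > object@nSubseq))
      return("non-N totals cannot exceed the subsequence count")
    TRUE
  })
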