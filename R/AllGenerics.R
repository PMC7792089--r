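#' Sequences of a binding-site set
#' @param x a \linkS4class{BindingSiteSet}.
#' @return a \link[Biostrings]{DNAStringSet}.
#' @export
setGeneric("siteSequences", function(x) standardGeneric("siteSequences"))

#' Labels of a binding-site set
#' @param x a \linkS4class{BindingSiteSet}.
#' @return factor with levels positive/negative.
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' Provenance of binding-site records
#' @param x a \linkS4class{BindingSiteSet}.
#' @export
setGeneric("siteSources", function(x) standardGeneric("siteSources"))

#' Length policy of a binding-site set
#' @param x a \linkS4class{BindingSiteSet}.
#' @export
setGeneric("sitePolicy", function(x) standardGeneric("sitePolicy"))

#' Architecture configuration of a capsule model
#' @param object a \linkS4class{CapsModel}.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' Binding scores for encoded fragments
#'
#' Runs the capsule network forward and returns, per fragment, the norms
#' of the two digit capsules.  The positive-capsule norm is the binding
#' score.
#'
#' @param model a \linkS4class{CapsModel}.
#' @param x sequences: character vector, \code{DNAStringSet}, or a
#'   \linkS4class{BindingSiteSet} (padded to the model's fragment length
#'   as needed).
#' @return numeric matrix with columns \code{scorePos}, \code{scoreNeg},
#'   each in [0, 1).
#' @export
setGeneric("predictScores", function(model, x) standardGeneric("predictScores"))

#' Per-fold AUC values
#' @param x a \linkS4class{CVResult}.
#' @export
setGeneric("foldAUC", function(x) standardGeneric("foldAUC"))

#' Counts of a position frequency matrix
#' @param x a \linkS4class{MotifPFM}.
#' @export
setGeneric("pfmCounts", function(x) standardGeneric("pfmCounts"))
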