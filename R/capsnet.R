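#' Construct an (untrained) capsule-network model
#'
#' Builds the classifier for fragments of a fixed length: \code{K}
#' convolutional motif detectors of width \code{h} (ReLU), global max
#' pooling (one scalar per detector), primary capsules of dimension
#' \code{dIn}, a per-(input, output) capsule affine transform into
#' \code{dOut}-dimensional space, and two digit capsules (bound /
#' unbound) computed by \code{T} rounds of dynamic routing.  With
#' pooling, the \code{K} pooled maxima reshape into \code{K / dIn}
#' primary capsules; with \code{maxpool = FALSE} every feature-map
#' position of each group of \code{dIn} detectors becomes a capsule, as
#' in the original capsule network.
#'
#' Weights are initialised from centred Gaussians under \code{seed}.
#'
#' @param thresholdL fragment length L the model accepts (nt).
#' @param kernelSize detector width h (default 9; 11 suits long
#'   fragments).
#' @param nFilters number of detectors K (default 128; must be a
#'   multiple of \code{capsDim}).
#' @param capsDim primary capsule dimension (default 8).
#' @param digitDim digit capsule dimension (default 16).
#' @param routingIters dynamic routing rounds T (default 2).
#' @param routingSoftmax coupling softmax axis: \code{"inputs"} (default;
#'   couplings over the n input capsules sum to 1 per digit capsule) or
#'   \code{"outputs"} (each input capsule's couplings over the digit
#'   capsules sum to 1, the original capsule-network convention).
#' @param maxpool use global max pooling (default TRUE).
#' @param mPlus,mMinus,lambda margin-loss constants (defaults 0.9, 0.1,
#'   0.5).
#' @param seed integer seed for weight initialisation.
#' @param initSd list of standard deviations for the conv and affine
#'   weights.
#' @return a \linkS4class{CapsModel}.
#' @export
capsModel <- function(thresholdL, kernelSize = 9L, nFilters = 128L,
                      capsDim = 8L, digitDim = 16L, routingIters = 2L,
                      routingSoftmax = c("inputs", "outputs"),
                      maxpool = TRUE, mPlus = 0.9, mMinus = 0.1,
                      lambda = 0.5, seed = 1L,
                      initSd = list(conv = 0.3, caps = 0.1)) {
  routingSoftmax <- match.arg(routingSoftmax)
  cfg <- list(L = as.integer(thresholdL), h = as.integer(kernelSize),
              K = as.integer(nFilters), dIn = as.integer(capsDim),
              dOut = as.integer(digitDim), nClass = 2L,
              T = as.integer(routingIters), maxpool = isTRUE(maxpool),
              softmaxAxis = routingSoftmax,
              mPlus = mPlus, mMinus = mMinus, lambda = lambda,
              alphabet = .ALPHABET)
  if (cfg$L < cfg$h) stop("fragment length must be at least the kernel size")
  if (cfg$K %% cfg$dIn != 0L)
    stop("nFilters must be a multiple of capsDim")
  n <- .nPrimaryCaps(cfg)
  withr::with_seed(as.integer(seed), {
    convW <- array(stats::rnorm(cfg$h * 4L * cfg$K, sd = initSd$conv),
                   dim = c(cfg$h, 4L, cfg$K))
    convB <- rep(0, cfg$K)
    capsW <- array(stats::rnorm(cfg$dOut * cfg$dIn * n * cfg$nClass,
                                sd = initSd$caps),
                   dim = c(cfg$dOut, cfg$dIn, n * cfg$nClass))
  })
  new("CapsModel", convW = convW, convB = convB, capsW = capsW, config = cfg)
}

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "CapsModel", function(object) object@config)

setMethod("show", "CapsModel", function(object) {
  cfg <- object@config
  n <- .nPrimaryCaps(cfg)
  cat("CapsModel: capsule-network binding-site classifier\n")
  cat(sprintf("  fragment length L = %d nt, %d detectors of width %d (ReLU)\n",
              cfg$L, cfg$K, cfg$h))
  cat(sprintf("  global max pooling: %s\n", if (cfg$maxpool) "yes" else "no"))
  cat(sprintf("  %d primary capsules (dim %d) -> %d digit capsules (dim %d), %d routing rounds\n",
              n, cfg$dIn, cfg$nClass, cfg$dOut, cfg$T))
  cat(sprintf("  margin loss: m+ = %g, m- = %g, lambda = %g\n",
              cfg$mPlus, cfg$mMinus, cfg$lambda))
})

.weightsList <- function(model) {
  list(convW = model@convW, convB = model@convB, capsW = model@capsW)
}

#' Convolutional feature maps of a fragment
#'
#' Applies motif detectors to a one-hot matrix: per detector the feature
#' map \eqn{[conf_1, ..., conf_{L-h+1}]} with
#' \eqn{conf_i = ReLU(\sum_j w_j x_j + b)}.  All-zero (N) rows contribute
#' nothing to the sum.
#'
#' @param M an L x 4 one-hot matrix (from \code{\link{encodeSequence}})
#'   or a nucleotide string.
#' @param filters \code{h x 4 x K} weight array (columns A, T, C, G), or
#'   a \linkS4class{CapsModel} whose detectors are used.
#' @param bias numeric detector biases (recycled to K); ignored when
#'   \code{filters} is a model.
#' @return numeric matrix \code{(L - h + 1) x K} of feature maps.
#' @export
convFeatures <- function(M, filters, bias = 0) {
  if (is.character(M)) M <- encodeSequence(M)
  s <- decodeSequence(M)
  if (is(filters, "CapsModel")) {
    w <- filters@convW
    bias <- filters@convB
  } else {
    w <- filters
    if (length(dim(w)) == 2L) w <- array(w, dim = c(dim(w), 1L))
  }
  h <- dim(w)[1L]; K <- dim(w)[3L]
  L <- nrow(M)
  if (L < h) stop("fragment is shorter than the detector width")
  bias <- rep_len(bias, K)
  cfg <- list(L = L, h = h, K = K, dIn = 1L, dOut = 1L, nClass = 1L,
              T = 1L, maxpool = TRUE, mPlus = 0.9, mMinus = 0.1, lambda = 0.5)
  capsW <- array(0, dim = c(1L, 1L, if (TRUE) K else 0L))
  .convMapsCpp(.seqCodes(s), list(convW = w, convB = bias, capsW = capsW), cfg)
}

#' Global max pooling of feature maps
#'
#' One scalar per detector: the maximum response over positions, with
#' the leftmost position retained on ties (used later for motif
#' discovery).
#'
#' @param maps numeric matrix \code{P x K} (positions x detectors) or a
#'   vector for a single detector.
#' @return list with \code{values} (length K) and \code{argmax}
#'   (1-based positions).
#' @export
globalMaxPool <- function(maps) {
  if (is.null(dim(maps))) maps <- matrix(maps, ncol = 1L)
  if (nrow(maps) == 0L) stop("feature maps must be non-empty")
  idx <- apply(maps, 2L, which.max)
  list(values = maps[cbind(idx, seq_len(ncol(maps)))], argmax = as.integer(idx))
}

#' Squashing nonlinearity
#'
#' Maps a capsule vector v to (||v||^2 / (1 + ||v||^2)) (v / ||v||):
#' direction preserved, norm squashed into [0, 1).  Evaluated as
#' v * ||v|| / (1 + ||v||^2), which is algebraically identical but never
#' divides by the norm, so the zero vector maps exactly to the zero
#' vector.
#'
#' @param v numeric vector.
#' @return squashed vector.
#' @export
squash <- function(v) {
  r2 <- sum(v * v)
  v * (sqrt(r2) / (1 + r2))
}

#' Dynamic routing between capsules
#'
#' For one digit capsule with transformed inputs \eqn{u^i}: starting from
#' zero logits, each round takes coupling coefficients as the softmax of
#' the logits over the n input capsules, forms the weighted aggregate
#' \eqn{a = \sum_i c_i u^i}, squashes it, and increments each logit by
#' the agreement \eqn{v \cdot u^i}.  Returns the round-T output and the
#' per-round couplings (positive, summing to 1 every round).
#'
#' @param u matrix of transformed input vectors, one column per input
#'   capsule (\code{d x n}), or a list of vectors.
#' @param iters number of routing rounds T (>= 1).
#' @return list with \code{v} (the routed output), \code{couplings}
#'   (\code{n x T}), \code{aggregates} and \code{outputs} per round.
#' @export
dynamicRouting <- function(u, iters = 2L) {
  if (is.list(u)) u <- do.call(cbind, u)
  if (!is.matrix(u)) u <- matrix(u, ncol = 1L)
  if (iters < 1L) stop("routing iterations must be >= 1")
  .routeCpp(u, as.integer(iters))
}

#' Margin loss for digit-capsule norms
#'
#' Per class c: \eqn{T_c \max(0, m^+ - \|v_c\|)^2 +
#' \lambda (1 - T_c) \max(0, \|v_c\| - m^-)^2}, summed over the two
#' classes.  Zero exactly when the true-class norm reaches \eqn{m^+} and
#' the other norm is at most \eqn{m^-}.
#'
#' @param scorePos,scoreNeg digit-capsule norms in [0, 1].
#' @param label \code{"positive"}/\code{"negative"} (or 1/0).
#' @param mPlus,mMinus,lambda loss constants (defaults 0.9, 0.1, 0.5).
#' @return scalar loss (vectorised over inputs).
#' @export
marginLoss <- function(scorePos, scoreNeg, label,
                       mPlus = 0.9, mMinus = 0.1, lambda = 0.5) {
  lab <- if (is.character(label) || is.factor(label))
    as.integer(as.character(label) == "positive") else as.integer(label)
  lossFor <- function(s, present) {
    ifelse(present,
           pmax(0, mPlus - s)^2,
           lambda * pmax(0, s - mMinus)^2)
  }
  lossFor(scorePos, lab == 1L) + lossFor(scoreNeg, lab == 0L)
}

#' @rdname predictScores
#' @export
setMethod("predictScores", signature("CapsModel", "ANY"), function(model, x) {
  cfg <- model@config
  if (is(x, "BindingSiteSet")) {
    codes <- .encodeSet(x)$codes
  } else {
    if (is(x, "XStringSet")) x <- as.character(x)
    padded <- vapply(x, function(s) {
      p <- padOrDiscard(s, lengthPolicy(cfg$L))
      if (is.null(p)) stop("a fragment is longer than the model's fragment length")
      p
    }, character(1))
    codes <- .codesMatrix(padded)
  }
  if (ncol(codes) != cfg$L) stop("fragment length mismatch with the model")
  sc <- .capsForwardCpp(codes, .weightsList(model), cfg)
  colnames(sc) <- c("scoreNeg", "scorePos")
  sc[, c("scorePos", "scoreNeg"), drop = FALSE]
})

#' Save a model checkpoint
#'
#' Writes a self-describing checkpoint: all weights plus the complete
#' configuration (alphabet order, architecture, routing and loss
#' constants, fragment length).  Reloading reproduces forward scores
#' bit-for-bit on the same platform.
#'
#' @param model a \linkS4class{CapsModel}.
#' @param path output file path (RDS).
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CapsModel"))
  saveRDS(list(format = "capsRBP-checkpoint", version = 1L,
               convW = model@convW, convB = model@convB,
               capsW = model@capsW, config = model@config),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint path written by \code{\link{saveModel}}.
#' @return a \linkS4class{CapsModel}.
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "capsRBP-checkpoint"))
    stop("not a capsRBP checkpoint")
  new("CapsModel", convW = x$convW, convB = x$convB, capsW = x$capsW,
      config = x$config)
}
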