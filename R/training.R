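#' ROC curve and AUC
#'
#' AUC via the Wilcoxon rank statistic: the probability that a random
#' positive outscores a random negative, with ties contributing 1/2.
#' The curve is computed over the distinct score thresholds.
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 (or factor/logical) class labels; both classes must
#'   be present.
#' @return list with \code{auc} and \code{curve}, a data frame of
#'   (\code{fpr}, \code{tpr}) points from (0,0) to (1,1).
#' @export
rocAuc <- function(scores, labels) {
  lab <- if (is.factor(labels) || is.character(labels))
    as.integer(as.character(labels) %in% c("1", "positive", "TRUE"))
  else as.integer(labels)
  if (length(scores) != length(lab)) stop("scores and labels differ in length")
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  auc <- (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- lab[ord]
  tp <- cumsum(l == 1L); fp <- cumsum(l == 0L)
  keep <- c(diff(s) != 0, TRUE)   # collapse tied thresholds
  curve <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(auc = auc, curve = curve)
}

# stratified fold assignment: each class split as evenly as possible
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a capsule-network model
#'
#' Minimises the margin loss with Adam over mini-batches.  A stratified
#' validation split (default 10\% of the training instances) is scored
#' after every epoch; training stops when the validation loss has not
#' improved for \code{patience} epochs, and the checkpoint with minimal
#' validation loss is returned.
#'
#' @param sites a \linkS4class{BindingSiteSet}, or a list with elements
#'   \code{codes} (integer matrix, one row per fragment) and
#'   \code{labels} (0/1).
#' @param model a \linkS4class{CapsModel}; when \code{NULL} one is built
#'   with \code{\link{capsModel}} defaults at the dataset's fragment
#'   length (extra arguments in \code{...} are passed through).
#' @param epochs maximum epochs (default 30).
#' @param batchSize mini-batch size; \code{NULL} picks 64, or 512 for
#'   datasets above 100,000 instances.
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2,adamEps Adam moment decays and epsilon.
#' @param patience epochs without validation improvement before stopping
#'   (default 3).
#' @param valFraction fraction of instances held out for validation
#'   (default 0.1, stratified).
#' @param seed integer seed controlling the validation split, weight
#'   initialisation (if the model is built here) and batch shuffling.
#' @param ... passed to \code{\link{capsModel}} when \code{model} is
#'   \code{NULL}.
#' @return list with \code{model} (the best checkpoint), \code{history}
#'   (data frame of per-epoch train/validation losses) and
#'   \code{bestEpoch}.
#' @export
trainModel <- function(sites, model = NULL, epochs = 30L, batchSize = NULL,
                       lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       adamEps = 1e-8, patience = 3L, valFraction = 0.1,
                       seed = 1L, ...) {
  enc <- if (is(sites, "BindingSiteSet")) .encodeSet(sites) else sites
  codes <- enc$codes; labels <- as.integer(enc$labels)
  N <- nrow(codes)
  if (is.null(batchSize)) batchSize <- if (N > 1e5) 512L else 64L
  withr::with_seed(as.integer(seed), {
    if (is.null(model))
      model <- capsModel(thresholdL = ncol(codes),
                         seed = sample.int(2^30, 1L), ...)
    # stratified validation split
    vidx <- unlist(lapply(split(seq_len(N), labels), function(ix) {
      nv <- max(1L, round(valFraction * length(ix)))
      sample(ix, nv)
    }), use.names = FALSE)
    tidx <- setdiff(seq_len(N), vidx)
    fit <- .capsTrainCpp(codes[tidx, , drop = FALSE], labels[tidx],
                         codes[vidx, , drop = FALSE], labels[vidx],
                         .weightsList(model), model@config,
                         list(lr = lr, beta1 = beta1, beta2 = beta2,
                              eps = adamEps, epochs = as.integer(epochs),
                              batch = as.integer(batchSize),
                              patience = as.integer(patience)))
  })
  trained <- new("CapsModel", convW = fit$weights$convW,
                 convB = fit$weights$convB, capsW = fit$weights$capsW,
                 config = model@config)
  list(model = trained,
       history = data.frame(epoch = seq_along(fit$trainLoss),
                            trainLoss = fit$trainLoss,
                            valLoss = fit$valLoss),
       bestEpoch = fit$bestEpoch)
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into k stratified folds; each fold in turn is held
#' out, a model is trained on the remaining k-1 folds (with an inner
#' stratified validation split for early stopping) and scored on the
#' held-out fold.  Reports per-fold ROC/AUC.
#'
#' @param sites a \linkS4class{BindingSiteSet}, or a list with
#'   \code{codes} and \code{labels} (e.g. for label-permutation
#'   controls).
#' @param k number of folds (default 5).
#' @param seed integer seed (fold assignment, initialisation, batching).
#' @param modelArgs named list passed to \code{\link{capsModel}}.
#' @param ... passed to \code{\link{trainModel}} (epochs, batchSize, lr,
#'   patience, ...).
#' @return a \linkS4class{CVResult}.
#' @export
crossValidate <- function(sites, k = 5L, seed = 1L, modelArgs = list(), ...) {
  if (k < 2L) stop("k must be >= 2")
  enc <- if (is(sites, "BindingSiteSet")) .encodeSet(sites) else sites
  labels <- enc$labels
  if (sum(labels == 1L) < k || sum(labels == 0L) < k)
    stop("need at least k positives and k negatives for k-fold CV")
  fold <- withr::with_seed(as.integer(seed), .stratifiedFolds(labels, k))
  scores <- numeric(length(labels))
  aucs <- numeric(k)
  curves <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    model <- do.call(capsModel, c(list(thresholdL = ncol(enc$codes),
                                       seed = seed * 1000L + f),
                                  modelArgs))
    fit <- trainModel(list(codes = enc$codes[tr, , drop = FALSE],
                           labels = labels[tr]),
                      model = model, seed = seed * 1000L + f, ...)
    sc <- .capsForwardCpp(enc$codes[te, , drop = FALSE],
                          .weightsList(fit$model), fit$model@config)
    scores[te] <- sc[, 2L]   # positive-capsule norm
    ra <- rocAuc(scores[te], labels[te])
    aucs[f] <- ra$auc
    curves[[f]] <- ra$curve
  }
  new("CVResult", foldAssignments = as.integer(fold), foldAUC = aucs,
      rocCurves = curves, scores = scores, labels = as.integer(labels))
}

#' @rdname foldAUC
#' @export
setMethod("foldAUC", "CVResult", function(x) x@foldAUC)

setMethod("show", "CVResult", function(object) {
  k <- length(object@foldAUC)
  cat(sprintf("CVResult: %d-fold cross-validation over %d instances\n",
              k, length(object@scores)))
  cat("  per-fold AUC:", paste(sprintf("%.4f", object@foldAUC), collapse = " "), "\n")
  cat(sprintf("  mean %.4f, median %.4f\n",
              mean(object@foldAUC), stats::median(object@foldAUC)))
})

#' Aggregate AUC of a cross-validation run
#'
#' AUC over the pooled held-out scores of all folds.
#'
#' @param x a \linkS4class{CVResult}.
#' @export
aggregateAUC <- function(x) {
  stopifnot(is(x, "CVResult"))
  rocAuc(x@scores, x@labels)$auc
}

#' Write per-fold CV metrics
#' @param x a \linkS4class{CVResult}.
#' @param path output TSV path.
#' @export
writeCVMetrics <- function(x, path) {
  df <- data.frame(fold = seq_along(x@foldAUC), auc = x@foldAUC)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pooled ROC points
#' @param x a \linkS4class{CVResult}.
#' @param path output TSV path.
#' @export
writeROCPoints <- function(x, path) {
  pts <- do.call(rbind, lapply(seq_along(x@rocCurves), function(f)
    cbind(fold = f, x@rocCurves[[f]])))
  utils::write.table(pts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
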