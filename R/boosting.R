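#' @include AllClasses.R
NULL

#' Weak-learner settings for the AdaBoost base trees
#'
#' Mirrors the decision-tree controls used with the boosted classifier:
#' maximum depth, minimum samples to split an internal node, minimum
#' samples per leaf, and the Gini impurity criterion. The controls apply
#' to whichever weak-learner backend is used ([giniTreeLearner()] by
#' default, [rpartLearner()] as an alternative; rpart clamps depths
#' above its hard limit of 30 -- inert in practice on under-sampled
#' training sets, which never support trees that deep).
#'
#' @param maxDepth maximum tree depth.
#' @param minSamplesSplit minimum node size to attempt a split.
#' @param minSamplesLeaf minimum observations in a leaf.
#' @param criterion split criterion; only `"gini"` is supported.
#' @return a `WeakLearnerSpec` list.
#' @seealso [adaBoostPreset()] for the per-network presets.
#' @export
weakLearnerSpec <- function(maxDepth = 5L, minSamplesSplit = 2L,
                            minSamplesLeaf = 1L, criterion = "gini") {
  if (!identical(criterion, "gini"))
    dtiValidationError("only the Gini impurity criterion is supported")
  if (maxDepth < 1L || minSamplesSplit < 1L || minSamplesLeaf < 1L)
    dtiValidationError("tree controls must be positive")
  structure(list(maxDepth = as.integer(maxDepth),
                 minSamplesSplit = as.integer(minSamplesSplit),
                 minSamplesLeaf = as.integer(minSamplesLeaf),
                 criterion = criterion),
            class = "WeakLearnerSpec")
}

#' Named tree presets per benchmark network and balancing method
#'
#' The tree controls used with each of the four benchmark networks under
#' random (`rus`) and cluster-based (`cus`) under-sampling.
#'
#' @param dataset one of `"enzymes"`, `"ion_channels"`, `"gpcrs"`,
#'   `"nuclear_receptors"`.
#' @param method `"rus"` or `"cus"`.
#' @return a [weakLearnerSpec()].
#' @export
adaBoostPreset <- function(dataset = c("enzymes", "ion_channels", "gpcrs",
                                       "nuclear_receptors"),
                           method = c("rus", "cus")) {
  dataset <- match.arg(dataset)
  method <- match.arg(method)
  tab <- list(
    rus = list(enzymes = c(100L, 16L, 1L), ion_channels = c(8L, 4L, 1L),
               gpcrs = c(6L, 3L, 1L), nuclear_receptors = c(5L, 7L, 2L)),
    cus = list(enzymes = c(110L, 1L, 1L), ion_channels = c(9L, 2L, 1L),
               gpcrs = c(6L, 3L, 1L), nuclear_receptors = c(150L, 2L, 1L)))
  p <- tab[[method]][[dataset]]
  weakLearnerSpec(maxDepth = p[1L], minSamplesSplit = p[2L],
                  minSamplesLeaf = p[3L])
}

#' Fit a discrete AdaBoost ensemble
#'
#' Classic discrete AdaBoost: start from the uniform distribution D_1,
#' fit the weak learner on (X, y, D_t) each round, compute the weighted
#' error `eps_t = sum_i D_t(i) 1[h_t(x_i) != y_i]`, set
#' `alpha_t = 0.5 * log((1 - eps_t) / eps_t)` and re-weight
#' `D_{t+1}(i) proportional to D_t(i) exp(-alpha_t y_i h_t(x_i))`. A round
#' with `eps_t = 0` is retained with alpha capped at
#' `0.5 * log((1 - 1e-10) / 1e-10)` and stops the loop; a round with
#' `eps_t >= 0.5` is discarded and stops the loop. An ensemble that
#' retains no stage at all is an error.
#'
#' @param X numeric feature matrix with named columns.
#' @param y -1/+1 labels.
#' @param spec a [weakLearnerSpec()] for the default tree learner.
#' @param nRounds number of boosting rounds T (default 100).
#' @param seed integer seed (relevant only for stochastic weak learners;
#'   the default trees are deterministic given weights).
#' @param learner weak-learner contract, a list with `fit(X, y, w)` and
#'   `predict(model, X)`; defaults to [giniTreeLearner()] built from
#'   `spec`, with [rpartLearner()] as a drop-in alternative.
#' @return a [BoostedEnsemble-class].
#' @examples
#' X <- cbind(x1 = c(-2, -1, 1, 2), x2 = c(0, 1, 0, 1))
#' y <- c(-1, -1, 1, 1)
#' m <- adaBoost(X, y, weakLearnerSpec(maxDepth = 1), nRounds = 5)
#' decisionFunction(m, X)
#' @export
adaBoost <- function(X, y, spec = weakLearnerSpec(), nRounds = 100L,
                     seed = 1L, learner = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (nrow(X) < 2L) dtiValidationError("need at least 2 training samples")
  if (length(unique(y)) < 2L)
    dtiValidationError("training labels must contain both classes")
  if (nRounds < 1L) dtiValidationError("nRounds must be >= 1")
  if (is.null(learner)) learner <- giniTreeLearner(spec)
  epsMin <- 1e-10
  n <- nrow(X)
  D <- rep(1 / n, n)
  stages <- list(); alphas <- numeric(0); errors <- numeric(0)
  withr::with_seed(seed, {
    for (t in seq_len(nRounds)) {
      h <- learner$fit(X, y, D)
      pred <- learner$predict(h, X)
      eps <- sum(D * (pred != y))
      if (eps >= 0.5) break            # no better than chance: discard, stop
      if (eps <= 0) {                  # perfect stage: retain capped, stop
        stages[[length(stages) + 1L]] <- h
        alphas <- c(alphas, 0.5 * log((1 - epsMin) / epsMin))
        errors <- c(errors, 0)
        break
      }
      alpha <- 0.5 * log((1 - eps) / eps)
      stages[[length(stages) + 1L]] <- h
      alphas <- c(alphas, alpha)
      errors <- c(errors, eps)
      D <- D * exp(-alpha * y * pred)
      D <- D / sum(D)
    }
  })
  if (!length(stages))
    dtiValidationError(paste(
      "AdaBoost retained no stage: the weak learner was no better than",
      "chance on round 1"))
  new("BoostedEnsemble", stages = stages, alphas = alphas, errors = errors,
      learner = learner, spec = unclass(spec),
      featureNames = colnames(X), nRounds = as.integer(nRounds))
}

.checkFeatures <- function(m, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(m@featureNames))
      dtiValidationError(sprintf(
        "feature count mismatch: model has %d, input has %d",
        length(m@featureNames), ncol(X)))
    colnames(X) <- m@featureNames
  } else if (!all(m@featureNames %in% colnames(X))) {
    dtiValidationError("input is missing model feature columns")
  } else {
    X <- X[, m@featureNames, drop = FALSE]
  }
  X
}

#' Ensemble decision function g(x)
#'
#' `g(x) = sum_t alpha_t h_t(x)`; `sign(g)` is the hard class prediction,
#' with ties (g = 0) resolved to +1.
#'
#' @param m a fitted [BoostedEnsemble-class].
#' @param X feature matrix.
#' @return numeric vector of real-valued margins.
#' @export
decisionFunction <- function(m, X) {
  stopifnot(is(m, "BoostedEnsemble"))
  X <- .checkFeatures(m, X)
  g <- numeric(nrow(X))
  for (t in seq_along(m@stages))
    g <- g + m@alphas[t] * m@learner$predict(m@stages[[t]], X)
  g
}

#' Hard class prediction
#'
#' @inheritParams decisionFunction
#' @return -1/+1 vector (`g = 0` maps to +1).
#' @export
predictLabel <- function(m, X) {
  ifelse(decisionFunction(m, X) >= 0, 1, -1)
}

#' Normalized prediction score in [0, 1]
#'
#' `(g(x) / sum(alpha) + 1) / 2`, a strictly monotone rescaling of the
#' margin; the induced ranking is identical to [decisionFunction()]. Used
#' for ROC/PR curves and for ranking candidate new interactions.
#'
#' @inheritParams decisionFunction
#' @return numeric vector in `[0, 1]`.
#' @export
predictScore <- function(m, X) {
  stopifnot(is(m, "BoostedEnsemble"))
  sumAlpha <- sum(m@alphas)
  if (sumAlpha <= 0) dtiValidationError("ensemble has no positive stage weight")
  (decisionFunction(m, X) / sumAlpha + 1) / 2
}

#' Save / load a fitted ensemble with metadata
#'
#' Serializes the ensemble together with its tree settings, stage weights
#' and errors to a portable RDS file.
#'
#' @param m a [BoostedEnsemble-class].
#' @param path file path.
#' @return `path` (`saveEnsemble`) or the restored ensemble
#'   (`loadEnsemble`), invisibly for the former.
#' @export
saveEnsemble <- function(m, path) {
  stopifnot(is(m, "BoostedEnsemble"))
  saveRDS(m, path)
  invisible(path)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(path) {
  m <- readRDS(path)
  if (!is(m, "BoostedEnsemble"))
    dtiParseError(paste0(path, " does not contain a BoostedEnsemble"))
  m
}
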