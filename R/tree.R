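#' @include AllClasses.R
NULL

# Depth-limited CART-style trees with instance weights and the Gini
# criterion, written matrix-first: the boosted ensemble refits a tree on
# re-weighted data every round, and on wide pair-feature matrices
# (1281-1476 columns) a formula-based fit spends most of its time in
# model.frame machinery rather than in splitting. The split search here
# is the standard exhaustive scan: per feature, sort, accumulate weighted
# class masses, and score every distinct-value boundary by weighted Gini
# decrease. rpart is available behind the same contract (rpartLearner)
# and is used as an independent cross-check in the tests.

# best (feature, threshold) by weighted Gini decrease; ties resolve to
# the lowest feature index, then the lowest threshold (deterministic)
.bestSplit <- function(X, y, w, minLeaf) {
  n <- nrow(X)
  wp <- w * (y == 1)
  Wp <- sum(wp); W <- sum(w); Wn <- W - Wp
  parentImp <- 2 * Wp * Wn / W
  best <- NULL
  bestGain <- 1e-12            # require a strictly positive decrease
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    o <- order(x)
    xs <- x[o]
    boundary <- which(xs[-n] < xs[-1L])
    if (!length(boundary)) next
    boundary <- boundary[boundary >= minLeaf & (n - boundary) >= minLeaf]
    if (!length(boundary)) next
    cw <- cumsum(w[o])[boundary]
    cp <- cumsum(wp[o])[boundary]
    cn <- cw - cp
    rw <- W - cw
    childImp <- 2 * (cp * cn / cw + (Wp - cp) * (Wn - cn) / rw)
    gain <- parentImp - childImp
    i <- which.max(gain)
    if (gain[i] > bestGain) {
      bestGain <- gain[i]
      best <- list(feature = j,
                   threshold = (xs[boundary[i]] + xs[boundary[i] + 1L]) / 2,
                   gain = gain[i])
    }
  }
  best
}

.growTree <- function(X, y, w, depth, spec) {
  wp <- sum(w[y == 1]); wn <- sum(w[y == -1])
  leaf <- list(leaf = TRUE, pred = if (wp >= wn) 1 else -1)
  if (depth >= spec$maxDepth || nrow(X) < spec$minSamplesSplit ||
      wp == 0 || wn == 0)
    return(leaf)
  sp <- .bestSplit(X, y, w, spec$minSamplesLeaf)
  if (is.null(sp)) return(leaf)
  goLeft <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = .growTree(X[goLeft, , drop = FALSE], y[goLeft], w[goLeft],
                        depth + 1L, spec),
       right = .growTree(X[!goLeft, , drop = FALSE], y[!goLeft],
                         w[!goLeft], depth + 1L, spec))
}

.predictTree <- function(node, X) {
  out <- numeric(nrow(X))
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- node$pred
    } else {
      goLeft <- X[idx, node$feature] <= node$threshold
      recurse(node$left, idx[goLeft])
      recurse(node$right, idx[!goLeft])
    }
  }
  recurse(node, seq_len(nrow(X)))
  out
}

#' Built-in weighted Gini tree weak learner
#'
#' The default weak-learner contract used by [adaBoost()]: a
#' depth-limited CART-style classification tree honoring instance
#' weights, split by weighted Gini impurity decrease with deterministic
#' tie-breaking. Returns a list with `fit(X, y, w)` and
#' `predict(model, X)`.
#'
#' @param spec a [weakLearnerSpec()].
#' @return a weak-learner contract list.
#' @seealso [rpartLearner()] for the rpart-backed alternative.
#' @export
giniTreeLearner <- function(spec = weakLearnerSpec()) {
  list(
    fit = function(X, y, w) .growTree(as.matrix(X), y, w, 0L, spec),
    predict = function(model, X) .predictTree(model, as.matrix(X)))
}

#' rpart-backed weak learner
#'
#' Same contract as [giniTreeLearner()] but grown by [rpart::rpart()]
#' (Gini splits, case weights, depth clamped to rpart's limit of 30).
#' Mostly useful as an independent reference implementation; the built-in
#' learner is considerably faster on wide feature matrices.
#'
#' @param spec a [weakLearnerSpec()].
#' @return a weak-learner contract list.
#' @export
rpartLearner <- function(spec = weakLearnerSpec()) {
  ctrl <- rpart::rpart.control(
    maxdepth = min(spec$maxDepth, 30L),
    minsplit = spec$minSamplesSplit,
    minbucket = spec$minSamplesLeaf,
    cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0, usesurrogate = 0)
  list(
    fit = function(X, y, w) {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c(-1, 1))
      rpart::rpart(.y ~ ., data = df, weights = w * length(y),
                   method = "class", parms = list(split = "gini"),
                   control = ctrl)
    },
    predict = function(model, X) {
      cls <- predict(model, as.data.frame(X), type = "class")
      ifelse(cls == "1", 1, -1)
    })
}
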