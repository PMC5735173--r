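#' @include AllClasses.R
NULL

#' Confusion counts for -1/+1 predictions
#'
#' @param yTrue,yPred equal-length -1/+1 vectors.
#' @return list with integer fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusionCounts <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    dtiValidationError("yTrue and yPred must have equal length")
  list(tp = sum(yTrue == 1 & yPred == 1),
       tn = sum(yTrue == -1 & yPred == -1),
       fp = sum(yTrue == -1 & yPred == 1),
       fn = sum(yTrue == 1 & yPred == -1))
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), precision TP/(TP+FP), specificity TN/(TN+FP),
#' false positive rate 1 - specificity, F1 = 2TP/(2TP+FP+FN), and the
#' Matthews correlation coefficient
#' ((TP*TN) - (FP*FN)) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A degenerate denominator (e.g. no positive predictions) yields 0 with
#' a warning, so cross-validation averages stay finite; an MCC with any
#' zero factor under the radical is likewise 0.
#'
#' @param cc confusion counts from [confusionCounts()].
#' @return named list: `sensitivity`, `precision`, `specificity`, `fpr`,
#'   `f1`, `mcc`.
#' @export
classificationMetrics <- function(cc) {
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("degenerate denominator for %s; returning 0", what))
      return(0)
    }
    num / den
  }
  sens <- safeDiv(cc$tp, cc$tp + cc$fn, "sensitivity")
  prec <- safeDiv(cc$tp, cc$tp + cc$fp, "precision")
  spc <- safeDiv(cc$tn, cc$tn + cc$fp, "specificity")
  f1 <- safeDiv(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn, "F1")
  mccDen <- (cc$tp + cc$fp) * (cc$tp + cc$fn) *
    (cc$tn + cc$fp) * (cc$tn + cc$fn)
  mcc <- if (mccDen == 0) 0 else
    (cc$tp * cc$tn - cc$fp * cc$fn) / sqrt(mccDen)
  list(sensitivity = sens, precision = prec, specificity = spc,
       fpr = 1 - spc, f1 = f1, mcc = mcc)
}

# tie-grouped cumulative TP/FP over descending score thresholds
.rankedCounts <- function(yTrue, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- yTrue[ord] == 1
  ends <- cumsum(rle(s)$lengths)   # last index of each tie group
  list(tp = cumsum(pos)[ends], fp = cumsum(!pos)[ends],
       n = ends, P = sum(pos), N = sum(!pos))
}

#' ROC curve and area
#'
#' True positive rate against false positive rate over all score
#' thresholds, tied scores grouped into a single threshold step; the area
#' is computed by the trapezoidal rule and equals the probability that a
#' random positive outranks a random negative (ties counted half). A
#' perfect ranking gives 1, an uninformative one 0.5.
#'
#' @param yTrue -1/+1 labels (both classes required).
#' @param scores real-valued scores, larger = more positive.
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
rocCurve <- function(yTrue, scores) {
  if (length(yTrue) != length(scores))
    dtiValidationError("labels and scores must have equal length")
  if (length(unique(yTrue)) < 2L)
    dtiValidationError("ROC requires both classes in yTrue")
  rc <- .rankedCounts(yTrue, scores)
  fpr <- c(0, rc$fp / rc$N)
  tpr <- c(0, rc$tp / rc$P)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and area
#'
#' Precision against recall over all score thresholds (tied scores
#' grouped). The area uses step-wise summation
#' `sum_i (R_i - R_{i-1}) * P_i` with no interpolation between points;
#' linear PR interpolation is known to overestimate. A ranking that is
#' pure noise scores about the positive prevalence; a perfect ranking
#' scores 1.
#'
#' @inheritParams rocCurve
#' @return list with `points` (data.frame `recall`, `precision`) and
#'   `auc`.
#' @export
prCurve <- function(yTrue, scores) {
  if (length(yTrue) != length(scores))
    dtiValidationError("labels and scores must have equal length")
  if (sum(yTrue == 1) < 1L)
    dtiValidationError("PR curve requires at least one positive")
  rc <- .rankedCounts(yTrue, scores)
  recall <- rc$tp / rc$P
  precision <- rc$tp / rc$n
  auc <- sum(diff(c(0, recall)) * precision)
  list(points = data.frame(recall = recall, precision = precision),
       auc = auc)
}

# stratified fold ids: within each class, shuffle then deal round-robin,
# keeping per-fold class proportions within one sample of the global ones
.stratifiedFolds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    members <- which(y == cl)
    if (length(members) < folds)
      dtiValidationError(sprintf(
        "class %s has %d members, fewer than %d folds",
        format(cl), length(members), folds))
    id[sample(members)] <- rep_len(seq_len(folds), length(members))
  }
  id
}

#' Repeated stratified cross-validation with train-only balancing
#'
#' Splits the pair set into stratified folds that each retain the global
#' imbalance ratio, applies the under-sampler to the training portion
#' only, fits AdaBoost, and scores the untouched test fold. Metrics per
#' fold: auROC, auPR and the threshold metrics of
#' [classificationMetrics()] at the given score cut-off. Reported
#' summaries are plain means over all folds x repeats. All randomness
#' (folds, sampling, clustering) derives from the single `seed`.
#'
#' @param X pair feature matrix (or a [PairFeatureMatrix-class]).
#' @param y -1/+1 labels (ignored when `X` is a PairFeatureMatrix).
#' @param sampler a [samplerConfig()], or a `function(X, y)` returning
#'   `list(X, y, idx)` for custom balancing.
#' @param spec a [weakLearnerSpec()] for the boosted trees.
#' @param nRounds boosting rounds per fold model.
#' @param folds number of folds (default 5).
#' @param repeats number of repetitions of the whole CV (default 5).
#' @param threshold score cut-off for the single-point metrics
#'   (default 0.5).
#' @param seed master seed.
#' @return a list of class `CVReport`: `perFold` data.frame, `summary`
#'   named means, `folds` fold-assignment list, and the call settings.
#' @export
crossValidate <- function(X, y = NULL, sampler = samplerConfig("rus"),
                          spec = weakLearnerSpec(), nRounds = 50L,
                          folds = 5L, repeats = 5L, threshold = 0.5,
                          seed = 1L) {
  if (is(X, "PairFeatureMatrix")) {
    y <- pairLabels(X)
    X <- featureMatrix(X)
  }
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    dtiValidationError("labels must align with feature rows")
  perFold <- NULL
  assignments <- vector("list", repeats)
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      foldId <- .stratifiedFolds(y, folds)
      assignments[[r]] <- foldId
      for (f in seq_len(folds)) {
        test <- foldId == f
        sampSeed <- sample.int(.Machine$integer.max, 1L)
        trainCfg <- if (is.function(sampler)) sampler else
          modifyList(sampler, list(seed = sampSeed))
        bal <- applySampler(X[!test, , drop = FALSE], y[!test], trainCfg)
        model <- adaBoost(bal$X, bal$y, spec = spec, nRounds = nRounds,
                          seed = sample.int(.Machine$integer.max, 1L))
        sc <- predictScore(model, X[test, , drop = FALSE])
        yTest <- y[test]
        mets <- suppressWarnings(classificationMetrics(
          confusionCounts(yTest, ifelse(sc >= threshold, 1, -1))))
        perFold <- rbind(perFold, data.frame(
          repeatIdx = r, fold = f,
          auROC = rocCurve(yTest, sc)$auc,
          auPR = prCurve(yTest, sc)$auc,
          sensitivity = mets$sensitivity, specificity = mets$specificity,
          precision = mets$precision, f1 = mets$f1, mcc = mets$mcc))
      }
    }
  })
  metricCols <- setdiff(names(perFold), c("repeatIdx", "fold"))
  structure(list(perFold = perFold,
                 summary = colMeans(perFold[metricCols]),
                 folds = assignments,
                 settings = list(folds = folds, repeats = repeats,
                                 nRounds = nRounds, threshold = threshold,
                                 seed = seed)),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  s <- x$settings
  cat(sprintf("CVReport: %d-fold x %d repeats (threshold %.2f)\n",
              s$folds, s$repeats, s$threshold))
  print(round(x$summary, 4))
  invisible(x)
}

#' Rank negative pairs as candidate new interactions
#'
#' High-scoring pairs labeled negative (closed-world non-edges) are the
#' natural candidates for undiscovered interactions: these are the
#' "false negatives" the classifier insists on calling positive. Sorts
#' the negative pairs by descending score with a stable lexicographic
#' (drugId, targetId) tie-break and returns the top `topN` (default 10).
#'
#' @param pairs data.frame with columns `drugId`, `targetId` (negative
#'   pairs only).
#' @param scores numeric scores aligned with `pairs` rows.
#' @param topN how many candidates to return; when more than available,
#'   all are returned with a warning.
#' @return data.frame `drugId`, `targetId`, `score`, best first.
#' @export
rankNewInteractions <- function(pairs, scores, topN = 10L) {
  if (nrow(pairs) != length(scores))
    dtiValidationError("pairs and scores must align")
  if (topN > nrow(pairs)) {
    warning(sprintf("requested top %d of %d pairs; returning all",
                    topN, nrow(pairs)))
    topN <- nrow(pairs)
  }
  ord <- order(-scores, pairs$drugId, pairs$targetId)
  out <- data.frame(drugId = pairs$drugId[ord], targetId = pairs$targetId[ord],
                    score = scores[ord], stringsAsFactors = FALSE)
  out <- out[seq_len(topN), , drop = FALSE]
  rownames(out) <- NULL
  out
}
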