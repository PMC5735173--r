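#' @include AllClasses.R
NULL

#' Build a bipartite drug-target interaction network
#'
#' Known interactions become the edge set; when the drug or target list is
#' omitted it is inferred from the interaction table (first-appearance
#' order). An interaction referencing an id missing from a supplied list
#' is an error.
#'
#' @param interactions data.frame with columns `drugId`, `targetId`
#'   (as returned by [readInteractions()]).
#' @param drugs optional character vector of drug ids.
#' @param targets optional character vector of target ids.
#' @return an [InteractionNetwork-class].
#' @examples
#' net <- buildNetwork(data.frame(drugId = "d1", targetId = "t1"),
#'                     drugs = c("d1", "d2"), targets = c("t1", "t2"))
#' net
#' @export
buildNetwork <- function(interactions, drugs = NULL, targets = NULL) {
  stopifnot(is.data.frame(interactions))
  if (!all(c("drugId", "targetId") %in% names(interactions)))
    dtiValidationError("interactions must have columns drugId, targetId")
  if (is.null(drugs)) drugs <- unique(interactions$drugId)
  if (is.null(targets)) targets <- unique(interactions$targetId)
  missD <- setdiff(interactions$drugId, drugs)
  if (length(missD))
    dtiValidationError(paste0("interaction references unknown drug: ",
                              missD[1L]))
  missT <- setdiff(interactions$targetId, targets)
  if (length(missT))
    dtiValidationError(paste0("interaction references unknown target: ",
                              missT[1L]))
  edges <- interactions[c("drugId", "targetId")]
  rownames(edges) <- NULL
  new("InteractionNetwork", drugs = as.character(drugs),
      targets = as.character(targets), edges = edges)
}

#' Enumerate the complete labeled pair set of a network
#'
#' Produces all |D| x |T| drug-target pairs in deterministic drug-major
#' order; a pair is labeled +1 exactly when it is a network edge and -1
#' otherwise (closed-world negatives).
#'
#' @param net an [InteractionNetwork-class].
#' @return a [LabeledPairSet-class] with `|D| * |T|` rows.
#' @export
enumeratePairs <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  if (!length(net@drugs) || !length(net@targets))
    dtiValidationError("network needs at least one drug and one target")
  pairs <- data.frame(
    drugId = rep(net@drugs, each = length(net@targets)),
    targetId = rep(net@targets, times = length(net@drugs)),
    stringsAsFactors = FALSE)
  edgeKey <- paste(net@edges$drugId, net@edges$targetId, sep = "\r")
  pairs$label <- ifelse(
    paste(pairs$drugId, pairs$targetId, sep = "\r") %in% edgeKey, 1, -1)
  new("LabeledPairSet", pairs = pairs)
}

#' Imbalance ratio of a labeled pair set
#'
#' Majority-class count divided by minority-class count. On the classic
#' benchmark geometries this ranges from about 14.6 (nuclear receptors,
#' 54 x 26 pairs, 90 positives) to 99.98 (enzymes).
#'
#' @param ps a [LabeledPairSet-class], or any -1/+1 label vector.
#' @return a single positive number.
#' @export
imbalanceRatio <- function(ps) {
  labels <- if (is(ps, "LabeledPairSet")) ps@pairs$label else ps
  nPos <- sum(labels == 1); nNeg <- sum(labels == -1)
  if (nPos == 0L || nNeg == 0L)
    dtiValidationError("both classes must be non-empty to define an imbalance ratio")
  max(nPos, nNeg) / min(nPos, nNeg)
}

#' Assemble the pair-level feature matrix
#'
#' Joins the drug fingerprint block (881 columns) with the target feature
#' vector for every labeled pair, in pair order. A pair whose drug or
#' target has no feature entry is an error (silent row dropping would
#' corrupt the imbalance statistics).
#'
#' @param ps a [LabeledPairSet-class].
#' @param drugBlocks named list of length-881 numeric vectors (e.g. from
#'   [fingerprintBlock()]), names = drug ids.
#' @param targetVectors named list of target feature vectors (equal
#'   lengths, e.g. from [extractTargetFeatures()]), names = target ids.
#' @param groups character vector recording which target groups the
#'   vectors contain (metadata only).
#' @return a [PairFeatureMatrix-class].
#' @export
assembleMatrix <- function(ps, drugBlocks, targetVectors,
                           groups = c("A", "B", "C", "D")) {
  stopifnot(is(ps, "LabeledPairSet"))
  pairs <- ps@pairs
  missD <- setdiff(unique(pairs$drugId), names(drugBlocks))
  if (length(missD))
    dtiValidationError(paste0("no drug features for id: ", missD[1L]))
  missT <- setdiff(unique(pairs$targetId), names(targetVectors))
  if (length(missT))
    dtiValidationError(paste0("no target features for id: ", missT[1L]))
  dLen <- unique(lengths(drugBlocks))
  tLen <- unique(lengths(targetVectors))
  if (length(dLen) != 1L || length(tLen) != 1L)
    dtiValidationError("feature vectors must have consistent lengths")
  dMat <- do.call(rbind, drugBlocks)[pairs$drugId, , drop = FALSE]
  tMat <- do.call(rbind, targetVectors)[pairs$targetId, , drop = FALSE]
  features <- cbind(dMat, tMat)
  rownames(features) <- NULL
  new("PairFeatureMatrix", features = features,
      labels = as.numeric(pairs$label),
      keys = pairs[c("drugId", "targetId")],
      groups = unique(toupper(groups)))
}
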