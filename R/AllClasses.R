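#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# PSSMProfile
# ---------------------------------------------------------------------------

#' Position-specific scoring matrix for one target protein
#'
#' Holds the L x 20 integer log-odds substitution matrix produced by
#' PSI-BLAST for a protein of length L, together with the sequence the
#' profile was computed for. Columns follow the PSI-BLAST amino-acid order
#' `A R N D C Q E G H I L K M F P S T W Y V`.
#'
#' @slot proteinId single identifier string.
#' @slot sequence amino-acid sequence of length L (L >= 2).
#' @slot scores L x 20 matrix of integer-valued substitution scores.
#'
#' @param proteinId,sequence,scores see slots.
#' @return `PSSMProfile()` returns a validated `PSSMProfile` object.
#' @seealso [readPSSM()], [normalizePSSM()], [pssmBigram()]
#' @examples
#' p <- makePSSM(length = 5, seed = 1)
#' dim(pssmScores(p))
#' @export PSSMProfile
#' @exportClass PSSMProfile
setClass("PSSMProfile",
  slots = c(proteinId = "character", sequence = "character",
            scores = "matrix"))

setValidity("PSSMProfile", function(object) {
  L <- nchar(object@sequence)
  msg <- character()
  if (length(object@proteinId) != 1L || !nzchar(object@proteinId))
    msg <- c(msg, "proteinId must be a single non-empty string")
  if (L < 2L)
    msg <- c(msg, "sequence must have length >= 2")
  if (ncol(object@scores) != 20L)
    msg <- c(msg, "scores must have exactly 20 columns")
  if (nrow(object@scores) != L)
    msg <- c(msg, "nrow(scores) must equal sequence length")
  if (anyNA(object@scores) || any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  else if (any(object@scores != round(object@scores)))
    msg <- c(msg, "scores must be integer-valued")
  if (length(msg)) msg else TRUE
})

PSSMProfile <- function(proteinId, sequence, scores) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  colnames(scores) <- PSSM_ALPHABET
  new("PSSMProfile", proteinId = as.character(proteinId),
      sequence = as.character(sequence), scores = scores)
}

#' @rdname accessors
#' @export
setMethod("proteinId", "PSSMProfile", function(x) x@proteinId)
#' @rdname accessors
#' @export
setMethod("proteinSequence", "PSSMProfile", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("pssmScores", "PSSMProfile", function(x) x@scores)

setMethod("show", "PSSMProfile", function(object) {
  cat("PSSMProfile '", object@proteinId, "': L = ",
      nchar(object@sequence), ", score range [",
      min(object@scores), ", ", max(object@scores), "]\n", sep = "")
})

# ---------------------------------------------------------------------------
# StructuralProfile
# ---------------------------------------------------------------------------

#' Predicted structural profile for one target protein (SPIDER2 output)
#'
#' Per-residue structural information as produced by SPIDER2: a
#' secondary-structure label (coil C, strand E, helix H), accessible
#' surface area in square Angstroms, the four backbone torsion angles
#' (phi, psi, theta, tau) in degrees, and the three structural class
#' probabilities P(C), P(E), P(H).
#'
#' @slot proteinId identifier string.
#' @slot sequence amino-acid sequence, length L.
#' @slot ss character vector of per-residue labels in `{C, E, H}`.
#' @slot asa numeric vector of accessible surface areas.
#' @slot angles L x 4 matrix of torsion angles in degrees, columns
#'   `phi, psi, theta, tau` (SPD file order).
#' @slot probs L x 3 row-stochastic matrix, columns `C, E, H`.
#'
#' @param proteinId,sequence,ss,asa,angles,probs see slots.
#' @return `StructuralProfile()` returns a validated object.
#' @seealso [readSPD()], [extractTargetFeatures()]
#' @export StructuralProfile
#' @exportClass StructuralProfile
setClass("StructuralProfile",
  slots = c(proteinId = "character", sequence = "character",
            ss = "character", asa = "numeric",
            angles = "matrix", probs = "matrix"))

setValidity("StructuralProfile", function(object) {
  L <- nchar(object@sequence)
  msg <- character()
  if (L < 1L) msg <- c(msg, "sequence must be non-empty")
  if (length(object@ss) != L || length(object@asa) != L ||
      nrow(object@angles) != L || nrow(object@probs) != L)
    msg <- c(msg, "all per-residue slots must share length L")
  if (!all(object@ss %in% SS_LABELS))
    msg <- c(msg, "ss labels must be in {C, E, H}")
  if (ncol(object@angles) != 4L)
    msg <- c(msg, "angles must have 4 columns (phi, psi, theta, tau)")
  if (any(abs(object@angles) > 360))
    msg <- c(msg, "angles must lie in [-360, 360] degrees")
  if (ncol(object@probs) != 3L)
    msg <- c(msg, "probs must have 3 columns (C, E, H)")
  if (any(object@probs < 0))
    msg <- c(msg, "probs must be non-negative")
  else if (nrow(object@probs) == L && L >= 1 &&
           any(abs(rowSums(object@probs) - 1) > 1e-3))
    msg <- c(msg, "each probs row must sum to 1 within 1e-3")
  if (length(msg)) msg else TRUE
})

StructuralProfile <- function(proteinId, sequence, ss, asa, angles, probs) {
  angles <- as.matrix(angles); storage.mode(angles) <- "double"
  probs <- as.matrix(probs); storage.mode(probs) <- "double"
  colnames(angles) <- ANGLE_NAMES
  colnames(probs) <- SS_LABELS
  new("StructuralProfile", proteinId = as.character(proteinId),
      sequence = as.character(sequence), ss = as.character(ss),
      asa = as.numeric(asa), angles = angles, probs = probs)
}

#' @rdname accessors
#' @export
setMethod("proteinId", "StructuralProfile", function(x) x@proteinId)
#' @rdname accessors
#' @export
setMethod("proteinSequence", "StructuralProfile", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("ssLabels", "StructuralProfile", function(x) x@ss)
#' @rdname accessors
#' @export
setMethod("asaValues", "StructuralProfile", function(x) x@asa)
#' @rdname accessors
#' @export
setMethod("torsionAngles", "StructuralProfile", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("structProbs", "StructuralProfile", function(x) x@probs)

setMethod("show", "StructuralProfile", function(object) {
  tab <- table(factor(object@ss, levels = SS_LABELS))
  cat("StructuralProfile '", object@proteinId, "': L = ",
      nchar(object@sequence), " (C/E/H = ", tab[["C"]], "/", tab[["E"]],
      "/", tab[["H"]], ")\n", sep = "")
})

# ---------------------------------------------------------------------------
# DrugFingerprint
# ---------------------------------------------------------------------------

#' 881-bit PubChem substructure fingerprint of a drug
#'
#' Fixed-length binary vector; bit i (0-based index i, stored at R position
#' i + 1) encodes presence (1) or absence (0) of the i-th PubChem
#' substructure key. Fingerprints are inputs to this package, never
#' computed by it (see [smilesToFingerprint()] for the optional adapter).
#'
#' @slot drugId identifier string.
#' @slot bits integer vector of length 881, values in \{0, 1\}.
#'
#' @param drugId,bits see slots.
#' @return `DrugFingerprint()` returns a validated object.
#' @seealso [readFingerprints()], [fingerprintBlock()]
#' @export DrugFingerprint
#' @exportClass DrugFingerprint
setClass("DrugFingerprint",
  slots = c(drugId = "character", bits = "integer"))

setValidity("DrugFingerprint", function(object) {
  msg <- character()
  if (length(object@drugId) != 1L || !nzchar(object@drugId))
    msg <- c(msg, "drugId must be a single non-empty string")
  if (length(object@bits) != FP_LENGTH)
    msg <- c(msg, sprintf("bits must have length %d, got %d",
                          FP_LENGTH, length(object@bits)))
  if (!all(object@bits %in% c(0L, 1L)))
    msg <- c(msg, "bits must be 0/1")
  if (length(msg)) msg else TRUE
})

DrugFingerprint <- function(drugId, bits) {
  new("DrugFingerprint", drugId = as.character(drugId),
      bits = as.integer(bits))
}

#' @rdname accessors
#' @export
setMethod("drugId", "DrugFingerprint", function(x) x@drugId)
#' @rdname accessors
#' @export
setMethod("fpBits", "DrugFingerprint", function(x) x@bits)

setMethod("show", "DrugFingerprint", function(object) {
  cat("DrugFingerprint '", object@drugId, "': ", sum(object@bits),
      "/", FP_LENGTH, " bits set\n", sep = "")
})

# ---------------------------------------------------------------------------
# InteractionNetwork / LabeledPairSet
# ---------------------------------------------------------------------------

#' Bipartite drug-target interaction network
#'
#' Vertices are the union of a drug set D and a target set T (disjoint id
#' namespaces); edges are the known (positive) interactions, a subset of
#' D x T.
#'
#' @slot drugs ordered character vector of drug ids.
#' @slot targets ordered character vector of target ids.
#' @slot edges data.frame with columns `drugId`, `targetId`.
#'
#' @seealso [buildNetwork()], [enumeratePairs()]
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  slots = c(drugs = "character", targets = "character",
            edges = "data.frame"))

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@drugs) || anyDuplicated(object@targets))
    msg <- c(msg, "drug and target ids must be unique")
  if (length(intersect(object@drugs, object@targets)))
    msg <- c(msg, "drug and target id namespaces must be disjoint")
  if (!all(c("drugId", "targetId") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns drugId, targetId")
  else {
    if (!all(object@edges$drugId %in% object@drugs))
      msg <- c(msg, "every edge drug must be a listed drug")
    if (!all(object@edges$targetId %in% object@targets))
      msg <- c(msg, "every edge target must be a listed target")
    if (anyDuplicated(paste(object@edges$drugId, object@edges$targetId,
                            sep = "\r")))
      msg <- c(msg, "duplicate edges are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("networkDrugs", "InteractionNetwork", function(x) x@drugs)
#' @rdname accessors
#' @export
setMethod("networkTargets", "InteractionNetwork", function(x) x@targets)
#' @rdname accessors
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork: |D| =", length(object@drugs),
      " |T| =", length(object@targets),
      " |E| =", nrow(object@edges), "\n")
})

#' Complete labeled drug-target pair set
#'
#' Every pair of the complete bipartite set D x T, labeled +1 if it is a
#' known interaction and -1 otherwise (closed-world assumption). Row order
#' is drug-major: all targets of the first drug, then the second drug, and
#' so on, in network input order.
#'
#' @slot pairs data.frame with columns `drugId`, `targetId`,
#'   `label` (+1/-1).
#'
#' @seealso [enumeratePairs()], [imbalanceRatio()]
#' @exportClass LabeledPairSet
setClass("LabeledPairSet", slots = c(pairs = "data.frame"))

setValidity("LabeledPairSet", function(object) {
  msg <- character()
  if (!all(c("drugId", "targetId", "label") %in% names(object@pairs)))
    msg <- c(msg, "pairs needs columns drugId, targetId, label")
  else if (!all(object@pairs$label %in% c(-1, 1)))
    msg <- c(msg, "labels must be -1 or +1")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("pairKeys", "LabeledPairSet",
          function(x) x@pairs[c("drugId", "targetId")])
#' @rdname accessors
#' @export
setMethod("pairLabels", "LabeledPairSet", function(x) x@pairs$label)
#' @rdname accessors
#' @export
setMethod("positiveCount", "LabeledPairSet",
          function(x) sum(x@pairs$label == 1))
#' @rdname accessors
#' @export
setMethod("negativeCount", "LabeledPairSet",
          function(x) sum(x@pairs$label == -1))

setMethod("show", "LabeledPairSet", function(object) {
  cat("LabeledPairSet:", nrow(object@pairs), "pairs (",
      positiveCount(object), "positive /", negativeCount(object),
      "negative )\n")
})

# ---------------------------------------------------------------------------
# PairFeatureMatrix
# ---------------------------------------------------------------------------

#' Pair-level feature matrix
#'
#' One row per labeled drug-target pair: the 881-bit drug fingerprint block
#' followed by the selected target feature groups. Column counts are 1281,
#' 1293, 1403 or 1476 for groups A, AB, ABC, ABCD.
#'
#' @slot features numeric matrix, one row per pair, named columns.
#' @slot labels numeric vector of -1/+1, aligned with rows.
#' @slot keys data.frame `drugId`, `targetId` per row.
#' @slot groups character vector of target feature groups used.
#'
#' @seealso [assembleMatrix()]
#' @exportClass PairFeatureMatrix
setClass("PairFeatureMatrix",
  slots = c(features = "matrix", labels = "numeric",
            keys = "data.frame", groups = "character"))

setValidity("PairFeatureMatrix", function(object) {
  msg <- character()
  if (nrow(object@features) != length(object@labels) ||
      nrow(object@features) != nrow(object@keys))
    msg <- c(msg, "features, labels and keys must align row-wise")
  if (!all(object@labels %in% c(-1, 1)))
    msg <- c(msg, "labels must be -1/+1")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("featureMatrix", "PairFeatureMatrix", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("pairLabels", "PairFeatureMatrix", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("pairKeys", "PairFeatureMatrix", function(x) x@keys)

setMethod("show", "PairFeatureMatrix", function(object) {
  cat("PairFeatureMatrix:", nrow(object@features), "pairs x",
      ncol(object@features), "features (groups",
      paste(object@groups, collapse = ""), ");",
      sum(object@labels == 1), "positive\n")
})

# ---------------------------------------------------------------------------
# BoostedEnsemble
# ---------------------------------------------------------------------------

#' Discrete AdaBoost ensemble
#'
#' Ordered stages (h_t, alpha_t) with decision function
#' g(x) = sum_t alpha_t h_t(x); sign(g) is the hard prediction. Every
#' retained stage has weighted training error eps_t < 0.5 and alpha_t > 0.
#'
#' @slot stages list of fitted weak hypotheses.
#' @slot alphas numeric stage weights alpha_t.
#' @slot errors numeric weighted training errors eps_t.
#' @slot learner the weak-learner contract used (list with fit/predict).
#' @slot spec the [weakLearnerSpec()] the trees were grown with.
#' @slot featureNames training feature names, enforced at prediction.
#' @slot nRounds requested number of boosting rounds T.
#'
#' @seealso [adaBoost()], [decisionFunction()], [predictScore()]
#' @exportClass BoostedEnsemble
setClass("BoostedEnsemble",
  slots = c(stages = "list", alphas = "numeric", errors = "numeric",
            learner = "list", spec = "list", featureNames = "character",
            nRounds = "integer"))

setValidity("BoostedEnsemble", function(object) {
  msg <- character()
  if (length(object@stages) != length(object@alphas) ||
      length(object@stages) != length(object@errors))
    msg <- c(msg, "stages, alphas and errors must have equal length")
  if (length(object@alphas) && any(object@alphas <= 0))
    msg <- c(msg, "all retained stage weights must be positive")
  if (length(object@errors) && any(object@errors >= 0.5))
    msg <- c(msg, "all retained stages must have error < 0.5")
  if (length(object@stages) > object@nRounds)
    msg <- c(msg, "cannot retain more stages than rounds")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("stageWeights", "BoostedEnsemble", function(x) x@alphas)
#' @rdname accessors
#' @export
setMethod("stageErrors", "BoostedEnsemble", function(x) x@errors)

setMethod("show", "BoostedEnsemble", function(object) {
  cat("BoostedEnsemble:", length(object@stages), "stages (of",
      object@nRounds, "rounds); sum(alpha) =",
      signif(sum(object@alphas), 4), "\n")
})
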