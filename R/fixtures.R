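#' @include AllClasses.R
NULL

# Synthetic-fixture generator. Emulates the four input kinds (PSSM, SPD,
# fingerprints, interaction list) with format-valid files, a configurable
# imbalance ratio and a plantable signal, so the whole pipeline is
# exercisable without any external data or tool. Only format and
# distributional shape are emulated, not real PSSM statistics or
# secondary-structure prediction accuracy.

.randomSequence <- function(length) {
  paste(sample(PSSM_ALPHABET, length, replace = TRUE), collapse = "")
}

#' Generate a synthetic PSSM profile (and optionally its ASCII file)
#'
#' Integer scores uniform on [-10, 10]; the written file round-trips
#' exactly through [readPSSM()]. Fully deterministic under `seed`
#' (byte-identical files).
#'
#' @param length protein length (>= 2).
#' @param seed integer seed.
#' @param path optional output path for the ASCII file.
#' @param proteinId identifier (default `"prot"`).
#' @param sequence optional fixed amino-acid sequence (overrides random).
#' @param shift integer added to a block of score columns; used to plant
#'   target-side signal (0 = none).
#' @return a [PSSMProfile-class].
#' @export
makePSSM <- function(length, seed, path = NULL, proteinId = "prot",
                     sequence = NULL, shift = 0) {
  stopifnot(length >= 2)
  withr::with_seed(seed, {
    if (is.null(sequence)) sequence <- .randomSequence(length)
    scores <- matrix(sample(-10:10, length * 20L, replace = TRUE),
                     nrow = length)
    if (shift != 0) {
      # bias the first 4 alphabet columns upward, clipped to the score range
      scores[, 1:4] <- pmin(10, scores[, 1:4] + round(shift))
    }
    prof <- PSSMProfile(proteinId, sequence, scores)
    if (!is.null(path)) writePSSM(prof, path)
    prof
  })
}

#' Generate a synthetic SPIDER2-style structural profile
#'
#' Angles uniform on [-180, 180] degrees, ASA uniform on [20, 200],
#' structural probabilities Dirichlet-like (normalized Gamma draws) and
#' the SS label set to the argmax of its probability row, so label and
#' probabilities are consistent by construction. Round-trips through
#' [readSPD()] within the file's decimal precision.
#'
#' @param length protein length (>= 2).
#' @param seed integer seed.
#' @param path optional output path for the SPD file.
#' @param proteinId identifier.
#' @param sequence optional fixed sequence.
#' @param helixBias added Gamma shape on the helix component; used to
#'   plant target-side structural signal (0 = none).
#' @return a [StructuralProfile-class].
#' @export
makeSPD <- function(length, seed, path = NULL, proteinId = "prot",
                    sequence = NULL, helixBias = 0) {
  stopifnot(length >= 2)
  withr::with_seed(seed, {
    if (is.null(sequence)) sequence <- .randomSequence(length)
    angles <- matrix(runif(length * 4L, -180, 180), ncol = 4L)
    asa <- runif(length, 20, 200)
    shape <- matrix(2, nrow = length, ncol = 3L)
    shape[, 3L] <- 2 + helixBias
    raw <- matrix(rgamma(length * 3L, shape = as.vector(shape)),
                  nrow = length)
    probs <- raw / rowSums(raw)
    ss <- SS_LABELS[max.col(probs, ties.method = "first")]
    prof <- StructuralProfile(proteinId, sequence, ss, asa, angles, probs)
    if (!is.null(path)) writeSPD(prof, path)
    prof
  })
}

#' Generate a random drug fingerprint
#'
#' Background bits are Bernoulli(`pOn`); when `signalBlock` is TRUE the
#' first 30 bits are set with probability `pSignal` instead, which is how
#' drug-side signal is planted.
#'
#' @param drugId identifier.
#' @param seed integer seed.
#' @param pOn background bit probability.
#' @param signalBlock plant the signal block?
#' @param pSignal on-probability of the 30 signal bits when planted.
#' @return a [DrugFingerprint-class].
#' @export
makeFingerprint <- function(drugId, seed, pOn = 0.1, signalBlock = FALSE,
                            pSignal = 0.95) {
  withr::with_seed(seed, {
    bits <- rbinom(FP_LENGTH, 1L, pOn)
    if (signalBlock) bits[1:30] <- rbinom(30L, 1L, pSignal)
    DrugFingerprint(drugId, bits)
  })
}

#' Fixture configuration
#'
#' @param nDrugs,nTargets network dimensions.
#' @param proteinLengthRange integer range of protein lengths; the
#'   minimum defaults to 12 so the auto-covariance precondition
#'   (length > df = 10) always holds.
#' @param density fraction of the |D| x |T| pairs that are positive
#'   edges (in (0, 1)).
#' @param signalStrength real >= 0 controlling the separation between
#'   positive-pair and negative-pair feature distributions; 0 plants no
#'   signal (edges uniform at random). Edge placement weights
#'   active-active pairs by `exp(signalStrength)`, so once that factor
#'   dwarfs the pair count (around 10 for desk-scale networks) placement
#'   is effectively deterministic on the planted block; the presets use
#'   10.
#' @param seed integer master seed.
#' @return a `FixtureConfig` list.
#' @export
fixtureConfig <- function(nDrugs, nTargets, proteinLengthRange = c(12L, 40L),
                          density = 0.1, signalStrength = 0, seed = 1L) {
  if (density <= 0 || density >= 1)
    dtiValidationError("density must be in (0, 1)")
  if (signalStrength < 0)
    dtiValidationError("signalStrength must be >= 0")
  if (proteinLengthRange[1L] < 11L)
    dtiValidationError("minimum protein length must exceed the df = 10 lag")
  structure(list(nDrugs = as.integer(nDrugs), nTargets = as.integer(nTargets),
                 proteinLengthRange = as.integer(proteinLengthRange),
                 density = density, signalStrength = signalStrength,
                 seed = as.integer(seed)),
            class = "FixtureConfig")
}

#' Generate a complete synthetic drug-target dataset
#'
#' Builds fingerprints, PSSM and SPD profiles for every drug and target,
#' and an interaction edge set at the requested density. Signal is
#' planted at the pair level: a subset of "active" drugs (signal bits in
#' the fingerprint) and "active" targets (shifted PSSM columns, helix
#' bias) is chosen so that active x active covers about `density` of all
#' pairs, and edges are drawn without replacement with weight
#' `exp(signalStrength)` on active-active pairs and 1 elsewhere. At
#' `signalStrength = 0` edges are uniform (no signal); at large values
#' nearly every edge is active-active, so a classifier that recovers the
#' planted activity separates the classes.
#'
#' When `outDir` is given, writes `fingerprints.csv`,
#' `interactions.csv`, `pssm/<target>.pssm` and `spd/<target>.spd`, all
#' parseable by the io functions.
#'
#' @param cfg a [fixtureConfig()].
#' @param outDir optional directory to write the fixture files into.
#' @return list with `network` ([InteractionNetwork-class]),
#'   `fingerprints` (named list), `pssms`, `spds` (named lists keyed by
#'   target id), `activeDrugs`, `activeTargets`, and `achievedRatio`.
#' @export
makeNetwork <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "FixtureConfig"))
  drugs <- sprintf("D%03d", seq_len(cfg$nDrugs))
  targets <- sprintf("hsa%03d", seq_len(cfg$nTargets))
  nPairs <- cfg$nDrugs * cfg$nTargets
  nEdges <- max(1L, round(cfg$density * nPairs))
  out <- withr::with_seed(cfg$seed, {
    # active sets sized so |active x active| ~ density * |D x T|
    frac <- sqrt(cfg$density)
    nad <- max(1L, round(cfg$nDrugs * frac))
    nat <- max(1L, round(cfg$nTargets * frac))
    activeDrugs <- drugs[sample.int(cfg$nDrugs, nad)]
    activeTargets <- targets[sample.int(cfg$nTargets, nat)]
    planted <- cfg$signalStrength > 0
    entitySeeds <- sample.int(2^30, cfg$nDrugs + 2L * cfg$nTargets)
    fingerprints <- lapply(seq_along(drugs), function(i)
      makeFingerprint(drugs[i], seed = entitySeeds[i],
                      signalBlock = planted && drugs[i] %in% activeDrugs,
                      pSignal = min(0.99, 0.1 + 0.18 * cfg$signalStrength)))
    names(fingerprints) <- drugs
    lens <- sample(seq(cfg$proteinLengthRange[1L], cfg$proteinLengthRange[2L]),
                   cfg$nTargets, replace = TRUE)
    pssms <- vector("list", cfg$nTargets)
    spds <- vector("list", cfg$nTargets)
    for (i in seq_along(targets)) {
      act <- planted && targets[i] %in% activeTargets
      sq <- .randomSequence(lens[i])
      pssms[[i]] <- makePSSM(lens[i], seed = entitySeeds[cfg$nDrugs + i],
                             proteinId = targets[i], sequence = sq,
                             shift = if (act) 2 * cfg$signalStrength else 0)
      spds[[i]] <- makeSPD(lens[i],
                           seed = entitySeeds[cfg$nDrugs + cfg$nTargets + i],
                           proteinId = targets[i], sequence = sq,
                           helixBias = if (act) 3 * cfg$signalStrength else 0)
    }
    names(pssms) <- targets
    names(spds) <- targets
    # weighted edge draw over the complete pair set
    pairD <- rep(drugs, each = cfg$nTargets)
    pairT <- rep(targets, times = cfg$nDrugs)
    w <- ifelse(pairD %in% activeDrugs & pairT %in% activeTargets,
                exp(cfg$signalStrength), 1)
    pick <- sample.int(nPairs, nEdges, prob = w)
    edges <- data.frame(drugId = pairD[pick], targetId = pairT[pick],
                        stringsAsFactors = FALSE)
    list(edges = edges, fingerprints = fingerprints, pssms = pssms,
         spds = spds, activeDrugs = activeDrugs,
         activeTargets = activeTargets)
  })
  net <- buildNetwork(out$edges, drugs = drugs, targets = targets)
  ratio <- (nPairs - nEdges) / nEdges
  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "pssm"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outDir, "spd"), recursive = TRUE,
               showWarnings = FALSE)
    writeFingerprints(out$fingerprints,
                      file.path(outDir, "fingerprints.csv"))
    writeLines(c("drug_id,target_id",
                 paste(out$edges$drugId, out$edges$targetId, sep = ",")),
               file.path(outDir, "interactions.csv"))
    for (t in targets) {
      writePSSM(out$pssms[[t]], file.path(outDir, "pssm",
                                          paste0(t, ".pssm")))
      writeSPD(out$spds[[t]], file.path(outDir, "spd", paste0(t, ".spd")))
    }
  }
  list(network = net, fingerprints = out$fingerprints, pssms = out$pssms,
       spds = out$spds, activeDrugs = out$activeDrugs,
       activeTargets = out$activeTargets, achievedRatio = ratio)
}

#' Named fixture presets
#'
#' `tiny` (20 x 12 pairs at density 0.1, strong planted signal) for fast
#' end-to-end tests; `nuclear_receptor_like` reproducing the 54 x 26 / 90
#' positives geometry (imbalance ratio 14.6); `enzyme_like` a scaled-down
#' network with an imbalance ratio near 100.
#'
#' @param preset preset name.
#' @param seed master seed.
#' @param signalStrength override of the preset's planted signal.
#' @param outDir optional directory to write the fixture files into.
#' @return as [makeNetwork()].
#' @export
makeFixtureDataset <- function(preset = c("tiny", "nuclear_receptor_like",
                                          "enzyme_like"),
                               seed = 1L, signalStrength = NULL,
                               outDir = NULL) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = fixtureConfig(20L, 12L, c(12L, 25L), density = 0.1,
                         signalStrength = 10, seed = seed),
    nuclear_receptor_like = fixtureConfig(54L, 26L, c(12L, 40L),
                                          density = 90 / (54 * 26),
                                          signalStrength = 10, seed = seed),
    enzyme_like = fixtureConfig(60L, 50L, c(12L, 40L), density = 0.0099,
                                signalStrength = 10, seed = seed))
  if (!is.null(signalStrength)) cfg$signalStrength <- signalStrength
  c(makeNetwork(cfg, outDir = outDir), list(config = cfg))
}

#' Turn a fixture dataset into a pair feature matrix
#'
#' Convenience wrapper: extracts drug blocks and target vectors from a
#' [makeNetwork()]/[makeFixtureDataset()] result and assembles the
#' [PairFeatureMatrix-class] for the requested feature groups.
#'
#' @param fx fixture list from [makeNetwork()] or [makeFixtureDataset()].
#' @param groups target feature groups (subset of A-D containing A).
#' @param df auto-covariance distance factor.
#' @param norm PSSM normalization method.
#' @return a [PairFeatureMatrix-class].
#' @export
fixtureFeatureMatrix <- function(fx, groups = c("A", "B", "C", "D"),
                                 df = 10L, norm = "sigmoid") {
  ps <- enumeratePairs(fx$network)
  drugBlocks <- lapply(fx$fingerprints, fingerprintBlock)
  targetVectors <- lapply(networkTargets(fx$network), function(t)
    extractTargetFeatures(fx$pssms[[t]], fx$spds[[t]], groups = groups,
                          df = df, norm = norm))
  names(targetVectors) <- networkTargets(fx$network)
  assembleMatrix(ps, drugBlocks, targetVectors, groups = groups)
}
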