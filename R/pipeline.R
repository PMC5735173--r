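#' @include AllClasses.R
NULL

.logStage <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [dtiBoost] ", ...)
}

.defaultPipelineConfig <- function() {
  list(
    fixtures = list(preset = "tiny"),
    inputs = NULL,       # list(pssm_dir=, spd_dir=, fingerprints=, interactions=)
    features = list(groups = c("A", "B", "C", "D"), df = 10,
                    normalization = "sigmoid"),
    balancing = list(method = "rus", k = 23, h = 1.0, targetRatio = 1.0,
                     allocation = "proportional"),
    # stumps by default: on small balanced training sets deeper trees hit
    # zero training error in round 1 and the ensemble degenerates to a
    # single hard stage with no ranking resolution
    boosting = list(preset = NULL, maxDepth = 1, minSamplesSplit = 2,
                    minSamplesLeaf = 1, nRounds = 20),
    evaluation = list(folds = 5, repeats = 5, threshold = 0.5, topN = 10),
    seed = 1)
}

#' Run the full training-and-evaluation pipeline
#'
#' Orchestrates the end-to-end flow: load (or synthesize) the inputs,
#' extract drug and target features, assemble the pair dataset, run
#' repeated stratified cross-validation with train-only balancing, train
#' a final model on the full (balanced) dataset and rank candidate new
#' interactions from the high-scoring negative pairs. Every stage logs
#' its row/column counts; all randomness derives from `config$seed`.
#'
#' Artifacts written to `outDir`: `features.csv` (+ `.json` sidecar with
#' network statistics and the echoed config), `cv.json`, `model.rds`,
#' `ranked_candidates.csv`, and `config.yaml`.
#'
#' @param config a nested configuration list (see
#'   `dtiBoost:::.defaultPipelineConfig()` for keys and defaults), or the
#'   path to a YAML file with the same structure. Partial configs are
#'   merged over the defaults.
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with `matrix` ([PairFeatureMatrix-class]),
#'   `cv` (`CVReport`), `model` ([BoostedEnsemble-class]) and
#'   `candidates` (ranked data.frame).
#' @examples
#' \donttest{
#' res <- runPipeline(list(evaluation = list(repeats = 1)),
#'                    outDir = tempfile())
#' res$cv$summary[["auROC"]]
#' }
#' @export
runPipeline <- function(config = list(), outDir = tempfile("dtiBoost")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(.defaultPipelineConfig(), config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    .logStage(sprintf("%s done in %.1fs", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  inputs <- stage("load-inputs", {
    if (!is.null(cfg$inputs)) {
      inter <- readInteractions(cfg$inputs$interactions)
      fps <- readFingerprints(cfg$inputs$fingerprints)
      targets <- unique(inter$targetId)
      pssms <- lapply(targets, function(t)
        readPSSM(file.path(cfg$inputs$pssm_dir, paste0(t, ".pssm")),
                 proteinId = t))
      spds <- lapply(targets, function(t)
        readSPD(file.path(cfg$inputs$spd_dir, paste0(t, ".spd")),
                proteinId = t))
      names(pssms) <- targets; names(spds) <- targets
      list(network = buildNetwork(inter, drugs = names(fps),
                                  targets = targets),
           fingerprints = fps, pssms = pssms, spds = spds)
    } else {
      makeFixtureDataset(cfg$fixtures$preset, seed = cfg$seed)
    }
  })
  .logStage(sprintf("network: |D| = %d, |T| = %d, |E| = %d",
                    length(networkDrugs(inputs$network)),
                    length(networkTargets(inputs$network)),
                    nrow(networkEdges(inputs$network))))

  pfm <- stage("extract-features", {
    fixtureFeatureMatrix(inputs, groups = cfg$features$groups,
                         df = cfg$features$df,
                         norm = cfg$features$normalization)
  })
  ps <- enumeratePairs(inputs$network)
  .logStage(sprintf("feature matrix: %d pairs x %d features (ratio %.2f)",
                    nrow(featureMatrix(pfm)), ncol(featureMatrix(pfm)),
                    imbalanceRatio(ps)))
  stage("write-dataset", writeFeatureMatrix(
    pfm, file.path(outDir, "features.csv"),
    sidecar = list(n_drugs = length(networkDrugs(inputs$network)),
                   n_targets = length(networkTargets(inputs$network)),
                   n_edges = nrow(networkEdges(inputs$network)),
                   imbalance_ratio = imbalanceRatio(ps),
                   config = cfg)))

  sampler <- samplerConfig(cfg$balancing$method, k = cfg$balancing$k,
                           h = cfg$balancing$h,
                           targetRatio = cfg$balancing$targetRatio,
                           allocation = cfg$balancing$allocation,
                           seed = cfg$seed)
  spec <- if (!is.null(cfg$boosting$preset)) {
    adaBoostPreset(cfg$boosting$preset, cfg$balancing$method)
  } else {
    weakLearnerSpec(cfg$boosting$maxDepth, cfg$boosting$minSamplesSplit,
                    cfg$boosting$minSamplesLeaf)
  }

  cv <- stage("cross-validate", crossValidate(
    pfm, sampler = sampler, spec = spec, nRounds = cfg$boosting$nRounds,
    folds = cfg$evaluation$folds, repeats = cfg$evaluation$repeats,
    threshold = cfg$evaluation$threshold, seed = cfg$seed))
  jsonlite::write_json(
    list(summary = as.list(cv$summary), perFold = cv$perFold,
         settings = cv$settings),
    file.path(outDir, "cv.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)

  model <- stage("train-final-model", {
    bal <- applySampler(featureMatrix(pfm), pairLabels(pfm), sampler)
    adaBoost(bal$X, bal$y, spec = spec, nRounds = cfg$boosting$nRounds,
             seed = cfg$seed)
  })
  saveEnsemble(model, file.path(outDir, "model.rds"))

  candidates <- stage("rank-new", {
    neg <- pairLabels(pfm) == -1
    sc <- predictScore(model, featureMatrix(pfm)[neg, , drop = FALSE])
    rankNewInteractions(pairKeys(pfm)[neg, , drop = FALSE], sc,
                        topN = cfg$evaluation$topN)
  })
  write.csv(candidates, file.path(outDir, "ranked_candidates.csv"),
            row.names = FALSE)

  invisible(list(matrix = pfm, cv = cv, model = model,
                 candidates = candidates))
}
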