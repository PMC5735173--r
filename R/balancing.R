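#' @include AllClasses.R
NULL

#' Under-sampler configuration
#'
#' @param method `"rus"` (uniform random under-sampling), `"cus"`
#'   (k-means cluster-based under-sampling) or `"none"`.
#' @param k number of k-means clusters for CUS; default 23, the best value
#'   found when sweeping k over 5..30 on the benchmark networks.
#' @param h under-sampling control for CUS: the total majority draw is
#'   `ceiling(h * targetRatio * n_minority)` (capped at the majority
#'   size); h = 1 draws the majority down to `targetRatio` times the
#'   minority.
#' @param targetRatio desired majority:minority ratio after sampling
#'   (default 1, i.e. a balanced training set).
#' @param allocation for CUS, how the total draw is spread over clusters:
#'   `"proportional"` to cluster sizes (largest-remainder rounding, every
#'   non-empty cluster contributes at least one row when the draw allows)
#'   or `"equal"` counts per cluster.
#' @param seed integer seed controlling both clustering and sampling.
#' @return a `SamplerConfig` list.
#' @seealso [randomUndersample()], [clusterUndersample()]
#' @export
samplerConfig <- function(method = c("rus", "cus", "none"), k = 23L,
                          h = 1.0, targetRatio = 1.0,
                          allocation = c("proportional", "equal"),
                          seed = 1L) {
  method <- match.arg(method)
  allocation <- match.arg(allocation)
  if (k < 1L) dtiValidationError("k must be >= 1")
  if (h <= 0) dtiValidationError("h must be positive")
  if (targetRatio <= 0) dtiValidationError("targetRatio must be positive")
  structure(list(method = method, k = as.integer(k), h = h,
                 targetRatio = targetRatio, allocation = allocation,
                 seed = as.integer(seed)),
            class = "SamplerConfig")
}

.splitClasses <- function(y) {
  if (length(unique(y)) < 2L)
    dtiValidationError("both classes must be present to under-sample")
  nPos <- sum(y == 1); nNeg <- sum(y == -1)
  majLabel <- if (nNeg >= nPos) -1 else 1
  list(majIdx = which(y == majLabel), minIdx = which(y != majLabel))
}

#' Random under-sampling of the majority class
#'
#' Keeps every minority row and draws majority rows uniformly without
#' replacement down to `ceiling(targetRatio * n_minority)` (capped at the
#' majority size). Deterministic under a fixed seed.
#'
#' @param X feature matrix (rows = samples).
#' @param y -1/+1 label vector aligned with rows of `X`.
#' @param cfg a [samplerConfig()]; only `targetRatio` and `seed` are used.
#' @return list with `X`, `y` and `idx` (the selected original row
#'   indices, minority first).
#' @export
randomUndersample <- function(X, y, cfg = samplerConfig("rus")) {
  cls <- .splitClasses(y)
  nDraw <- min(length(cls$majIdx),
               ceiling(cfg$targetRatio * length(cls$minIdx)))
  drawn <- withr::with_seed(cfg$seed,
    sample(cls$majIdx, nDraw, replace = FALSE))
  idx <- c(cls$minIdx, sort(drawn))
  list(X = X[idx, , drop = FALSE], y = y[idx], idx = idx)
}

# split nDraw over cluster sizes; guarantees alloc <= sizes and, when
# nDraw >= number of non-empty clusters, alloc >= 1 everywhere
.allocateDraw <- function(sizes, nDraw, allocation = "proportional") {
  nc <- length(sizes)
  quota <- if (allocation == "proportional") {
    nDraw * sizes / sum(sizes)
  } else {
    rep(nDraw / nc, nc)
  }
  alloc <- floor(quota)
  rem <- nDraw - sum(alloc)
  if (rem > 0) {
    # largest fractional remainders first; ties to larger clusters
    ord <- order(quota - alloc, sizes, decreasing = TRUE)
    take <- ord[seq_len(rem)]
    alloc[take] <- alloc[take] + 1L
  }
  # cap at cluster sizes and redistribute overflow
  repeat {
    over <- alloc > sizes
    if (!any(over)) break
    excess <- sum(alloc[over] - sizes[over])
    alloc[over] <- sizes[over]
    spare <- which(alloc < sizes)
    if (!length(spare) || excess == 0) break
    ord <- spare[order(quota[spare] - alloc[spare], decreasing = TRUE)]
    for (i in rep(ord, length.out = excess))
      if (alloc[i] < sizes[i]) alloc[i] <- alloc[i] + 1L
  }
  # every non-empty cluster represented when the draw allows it
  if (nDraw >= nc) {
    while (any(alloc == 0 & sizes > 0)) {
      need <- which(alloc == 0 & sizes > 0)[1L]
      donor <- which.max(alloc)
      if (alloc[donor] <= 1L) break
      alloc[donor] <- alloc[donor] - 1L
      alloc[need] <- 1L
    }
  }
  alloc
}

#' Cluster-based under-sampling (CUS) of the majority class
#'
#' The majority class is partitioned with k-means (Euclidean, seeded,
#' 10 restarts, 300-iteration cap) and the total draw
#' `min(n_majority, ceiling(h * targetRatio * n_minority))` is spread over
#' the clusters -- proportionally to cluster size by default -- with
#' uniform sampling without replacement inside each cluster, so the drawn
#' subsample represents the whole majority class. Minority rows are never
#' touched. With `k = 1` this reduces to [randomUndersample()].
#'
#' @inheritParams randomUndersample
#' @param cfg a [samplerConfig()]; uses `k`, `h`, `targetRatio`,
#'   `allocation`, `seed`.
#' @return list with `X`, `y`, `idx` and `clusters` (cluster id of each
#'   drawn majority row).
#' @export
clusterUndersample <- function(X, y, cfg = samplerConfig("cus")) {
  cls <- .splitClasses(y)
  nMaj <- length(cls$majIdx)
  if (nMaj < cfg$k)
    dtiValidationError(sprintf(
      "majority class has %d rows, fewer than k = %d clusters; use a smaller k",
      nMaj, cfg$k))
  Xmaj <- X[cls$majIdx, , drop = FALSE]
  nDraw <- min(nMaj, ceiling(cfg$h * cfg$targetRatio * length(cls$minIdx)))
  res <- withr::with_seed(cfg$seed, {
    kEff <- min(cfg$k, nrow(unique(Xmaj)))
    cl <- if (kEff == 1L) {
      list(cluster = rep(1L, nMaj))
    } else {
      stats::kmeans(Xmaj, centers = kEff, nstart = 10L, iter.max = 300L)
    }
    sizes <- tabulate(cl$cluster, nbins = max(cl$cluster))
    alloc <- .allocateDraw(sizes, nDraw, cfg$allocation)
    drawn <- integer(0)
    for (c in seq_along(alloc)) {
      members <- which(cl$cluster == c)
      if (alloc[c] > 0)
        drawn <- c(drawn, members[sample.int(length(members), alloc[c])])
    }
    list(drawn = sort(drawn), cluster = cl$cluster)
  })
  idx <- c(cls$minIdx, cls$majIdx[res$drawn])
  list(X = X[idx, , drop = FALSE], y = y[idx], idx = idx,
       clusters = res$cluster[res$drawn])
}

#' Apply a sampler configuration to a training set
#'
#' Dispatches on `cfg$method`; `"none"` returns the input unchanged. Used
#' internally by [crossValidate()] so that balancing only ever sees
#' training rows.
#'
#' @inheritParams randomUndersample
#' @return list with `X`, `y`, `idx`.
#' @export
applySampler <- function(X, y, cfg) {
  if (is.function(cfg)) return(cfg(X, y))
  switch(cfg$method,
    none = list(X = X, y = y, idx = seq_along(y)),
    rus = randomUndersample(X, y, cfg),
    cus = clusterUndersample(X, y, cfg))
}
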