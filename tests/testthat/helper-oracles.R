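# Independent brute-force oracles, kept deliberately naive (explicit
# double loops, exhaustive threshold enumeration) so they share no code
# path with the implementations they check.

oracleBigram <- function(M) {
  M <- unname(as.matrix(M))
  L <- nrow(M); d <- ncol(M)
  out <- matrix(0, d, d)
  for (k in seq_len(d)) for (l in seq_len(d)) {
    s <- 0
    for (i in seq_len(L - 1)) s <- s + M[i, k] * M[i + 1, l]
    out[k, l] <- s / L
  }
  out
}

# j-outer / k-inner flatten, matching the feature layout
oracleAutoCovariance <- function(M, df) {
  M <- unname(as.matrix(M))
  L <- nrow(M); d <- ncol(M)
  out <- numeric(0)
  for (j in seq_len(d)) for (k in seq_len(df)) {
    s <- 0
    for (i in seq_len(L - k)) s <- s + M[i, j] * M[i + k, j]
    out <- c(out, s / L)
  }
  out
}

# auROC as the Mann-Whitney U statistic / (P*N), ties counted half
oracleAuROC <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == -1]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# step-wise auPR by exhaustive enumeration of distinct-score thresholds
oracleAuPR <- function(y, s) {
  thr <- sort(unique(s), decreasing = TRUE)
  P <- sum(y == 1)
  lastR <- 0; area <- 0
  for (t in thr) {
    called <- s >= t
    tp <- sum(called & y == 1)
    r <- tp / P
    p <- tp / sum(called)
    area <- area + (r - lastR) * p
    lastR <- r
  }
  area
}

oracleConfusion <- function(yTrue, yPred) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(yTrue)) {
    if (yTrue[i] == 1 && yPred[i] == 1) tp <- tp + 1
    if (yTrue[i] == -1 && yPred[i] == -1) tn <- tn + 1
    if (yTrue[i] == -1 && yPred[i] == 1) fp <- fp + 1
    if (yTrue[i] == 1 && yPred[i] == -1) fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# random row-stochastic matrix (Dirichlet-ish rows)
randomStochastic <- function(L, d = 3) {
  m <- matrix(rgamma(L * d, 2), L, d)
  m / rowSums(m)
}

randomStructuralProfile <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- randomStochastic(L)
  StructuralProfile(
    proteinId = "p", sequence = paste(rep("A", L), collapse = ""),
    ss = c("C", "E", "H")[max.col(probs)],
    asa = runif(L, 0, 200),
    angles = matrix(runif(L * 4, -180, 180), L, 4),
    probs = probs)
}
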