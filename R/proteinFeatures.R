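#' @include AllClasses.R
NULL

# Target-protein feature encoders. All bigram-style encoders divide by L
# (the protein length) even though their sums run over L-1 adjacent pairs
# or L-k lagged pairs; that is the printed definition and it is kept
# verbatim so feature values are comparable across implementations.

#' Normalize a PSSM score matrix to [0, 1]
#'
#' Two squashing conventions are offered. `sigmoid` (the default) applies
#' the logistic function 1/(1 + exp(-m)) element-wise, the usual treatment
#' of log-odds substitution scores. `minmax` rescales linearly by the
#' global matrix minimum and maximum and fails on a constant matrix.
#'
#' @param pssm a [PSSMProfile-class].
#' @param method `"sigmoid"` or `"minmax"`.
#' @return L x 20 numeric matrix with entries in `[0, 1]`.
#' @examples
#' p <- makePSSM(length = 4, seed = 1)
#' range(normalizePSSM(p))
#' @export
normalizePSSM <- function(pssm, method = c("sigmoid", "minmax")) {
  stopifnot(is(pssm, "PSSMProfile"))
  method <- match.arg(method)
  m <- pssm@scores
  if (method == "sigmoid") {
    n <- 1 / (1 + exp(-m))
  } else {
    rng <- range(m)
    if (rng[1] == rng[2])
      dtiValidationError("minmax normalization is degenerate on a constant matrix")
    n <- (m - rng[1]) / (rng[2] - rng[1])
  }
  dimnames(n) <- list(NULL, PSSM_ALPHABET)
  n
}

# shared adjacent-bigram kernel: B[k, l] = (1/L) sum_i M[i,k] M[i+1,l]
.bigram <- function(M) {
  L <- nrow(M)
  if (L < 2L)
    dtiValidationError("bigram features require at least 2 residues")
  crossprod(M[-L, , drop = FALSE], M[-1L, , drop = FALSE]) / L
}

# row-major flatten of a k x l matrix with names <prefix>_k_l
.flattenRowMajor <- function(B, prefix) {
  v <- as.vector(t(B))
  kk <- rep(seq_len(nrow(B)), each = ncol(B))
  ll <- rep(seq_len(ncol(B)), times = nrow(B))
  names(v) <- paste(prefix, kk, ll, sep = "_")
  v
}

#' PSSM bigram features (400 values)
#'
#' `PSSM-bigram(k, l) = (1/L) * sum_{i=1}^{L-1} N[i,k] * N[i+1,l]` for all
#' 20 x 20 amino-acid column pairs of the normalized profile, flattened
#' row-major (k outer, l inner) in PSI-BLAST alphabet order.
#'
#' @param n normalized L x 20 matrix from [normalizePSSM()].
#' @return named numeric vector of length 400 (`pssm_bg_<k>_<l>`).
#' @export
pssmBigram <- function(n) {
  n <- as.matrix(n)
  if (ncol(n) != 20L)
    dtiValidationError("normalized PSSM must have 20 columns")
  .flattenRowMajor(.bigram(n), "pssm_bg")
}

#' Secondary-structure composition (3 values)
#'
#' Normalized frequency of the coil (C), strand (E) and helix (H) labels,
#' in that fixed order; the three values sum to 1.
#'
#' @param sp a [StructuralProfile-class].
#' @return named numeric vector `ss_comp_C`, `ss_comp_E`, `ss_comp_H`.
#' @export
ssComposition <- function(sp) {
  stopifnot(is(sp, "StructuralProfile"))
  v <- as.numeric(table(factor(sp@ss, levels = SS_LABELS))) / length(sp@ss)
  names(v) <- paste0("ss_comp_", SS_LABELS)
  v
}

#' Accessible-surface-area composition (1 value)
#'
#' The arithmetic mean of the per-residue ASA vector.
#'
#' @param sp a [StructuralProfile-class].
#' @return named numeric scalar `asa_comp`.
#' @export
asaComposition <- function(sp) {
  stopifnot(is(sp, "StructuralProfile"))
  c(asa_comp = mean(sp@asa))
}

#' Sine/cosine transform of the torsion angles
#'
#' Converts the four torsion angles (phi, psi, theta, tau; degrees) to
#' radians and returns the L x 8 matrix `[sin(phi) sin(psi) sin(theta)
#' sin(tau) cos(phi) cos(psi) cos(theta) cos(tau)]`. All downstream
#' torsion-angle features are computed on this matrix, so every one of
#' them is invariant under adding full turns (360 degrees) to any angle.
#'
#' @param sp a [StructuralProfile-class].
#' @return L x 8 numeric matrix with entries in `[-1, 1]`.
#' @export
torsionTransform <- function(sp) {
  stopifnot(is(sp, "StructuralProfile"))
  rad <- sp@angles * pi / 180
  out <- cbind(sin(rad), cos(rad))
  colnames(out) <- c(paste0("sin_", ANGLE_NAMES), paste0("cos_", ANGLE_NAMES))
  out
}

#' Torsion-angle composition (8 values)
#'
#' Column means of the sine/cosine torsion matrix.
#'
#' @param t L x 8 matrix from [torsionTransform()].
#' @return named numeric vector of length 8 (`ta_comp_1` ... `ta_comp_8`).
#' @export
taComposition <- function(t) {
  t <- as.matrix(t)
  if (ncol(t) != 8L) dtiValidationError("torsion matrix must have 8 columns")
  v <- colMeans(t)
  names(v) <- paste0("ta_comp_", 1:8)
  v
}

#' Torsion-angle bigram (64 values)
#'
#' `TA-bigram(k, l) = (1/L) * sum_{i=1}^{L-1} T[i,k] * T[i+1,l]`,
#' flattened row-major over the 8 x 8 column pairs.
#'
#' @param t L x 8 matrix from [torsionTransform()].
#' @return named numeric vector of length 64 (`ta_bg_<k>_<l>`).
#' @export
taBigram <- function(t) {
  t <- as.matrix(t)
  if (ncol(t) != 8L) dtiValidationError("torsion matrix must have 8 columns")
  .flattenRowMajor(.bigram(t), "ta_bg")
}

#' Structural-probability bigram (9 values)
#'
#' `SP-bigram(k, l) = (1/L) * sum_{i=1}^{L-1} P[i,k] * P[i+1,l]` over the
#' 3 x 3 pairs of structural probability columns (C, E, H), row-major.
#' Because the probability rows sum to 1, the nine values sum to (L-1)/L.
#'
#' @param sp a [StructuralProfile-class].
#' @return named numeric vector of length 9 (`sp_bg_<k>_<l>`).
#' @export
spBigram <- function(sp) {
  stopifnot(is(sp, "StructuralProfile"))
  .flattenRowMajor(.bigram(sp@probs), "sp_bg")
}

# lagged auto-covariance: A[k, j] = (1/L) sum_{i=1}^{L-k} M[i,j] M[i+k,j];
# flattened j-outer / k-inner
.autoCovariance <- function(M, df, prefix) {
  L <- nrow(M); d <- ncol(M)
  if (L <= df)
    dtiValidationError(sprintf(
      "auto-covariance with df = %d needs protein length > %d (got %d)",
      df, df, L))
  out <- numeric(d * df)
  nm <- character(d * df)
  pos <- 0L
  for (j in seq_len(d)) {
    for (k in seq_len(df)) {
      pos <- pos + 1L
      out[pos] <- sum(M[seq_len(L - k), j] * M[seq_len(L - k) + k, j]) / L
      nm[pos] <- paste(prefix, k, j, sep = "_")
    }
  }
  names(out) <- nm
  out
}

#' Torsion-angle auto-covariance (8 * df values)
#'
#' `TA-AC(k, j) = (1/L) * sum_{i=1}^{L-k} T[i,j] * T[i+k,j]` for lags
#' k = 1..df and each of the 8 sine/cosine columns, flattened with the
#' column index outer and the lag inner. The distance factor defaults to
#' df = 10 (80 values); proteins must be longer than df residues.
#'
#' @param t L x 8 matrix from [torsionTransform()].
#' @param df distance factor (maximum lag), default 10.
#' @return named numeric vector of length `8 * df` (`ta_ac_<k>_<j>`).
#' @export
taAutoCovariance <- function(t, df = 10L) {
  t <- as.matrix(t)
  if (ncol(t) != 8L) dtiValidationError("torsion matrix must have 8 columns")
  .autoCovariance(t, as.integer(df), "ta_ac")
}

#' Structural-probability auto-covariance (3 * df values)
#'
#' Same lagged recurrence as [taAutoCovariance()] applied to the three
#' structural-probability columns; 30 values at the default df = 10.
#'
#' @param sp a [StructuralProfile-class].
#' @param df distance factor (maximum lag), default 10.
#' @return named numeric vector of length `3 * df` (`sp_ac_<k>_<j>`).
#' @export
spAutoCovariance <- function(sp, df = 10L) {
  stopifnot(is(sp, "StructuralProfile"))
  .autoCovariance(sp@probs, as.integer(df), "sp_ac")
}

#' Extract the target-side feature vector for a protein
#'
#' Concatenates the selected feature groups in fixed order:
#' \describe{
#'   \item{A}{PSSM bigram (400)}
#'   \item{B}{SS composition (3), ASA composition (1), TA composition (8)}
#'   \item{C}{TA auto-covariance (8 df), SP auto-covariance (3 df)}
#'   \item{D}{TA bigram (64), SP bigram (9)}
#' }
#' Groups B, C and D are only ever added on top of the base group A, so
#' the target-side vector length is 400, 412, 522 or 595 for A, AB, ABC,
#' ABCD at df = 10 (1281/1293/1403/1476 once the 881-bit drug block is
#' prepended at the pair level).
#'
#' @param pssm a [PSSMProfile-class].
#' @param sp the matching [StructuralProfile-class] (same protein).
#' @param groups subset of `c("A","B","C","D")` containing `"A"`.
#' @param df distance factor for the auto-covariance groups.
#' @param norm normalization method passed to [normalizePSSM()].
#' @return named numeric feature vector.
#' @examples
#' p <- makePSSM(length = 15, seed = 1)
#' s <- makeSPD(length = 15, seed = 1, sequence = proteinSequence(p))
#' length(extractTargetFeatures(p, s, groups = c("A", "B", "C", "D")))
#' @export
extractTargetFeatures <- function(pssm, sp, groups = c("A", "B", "C", "D"),
                                  df = 10L, norm = "sigmoid") {
  stopifnot(is(pssm, "PSSMProfile"), is(sp, "StructuralProfile"))
  groups <- unique(toupper(groups))
  if (!all(groups %in% c("A", "B", "C", "D")))
    dtiValidationError("groups must be a subset of {A, B, C, D}")
  if (!"A" %in% groups)
    dtiValidationError("group A (PSSM bigram) is the base group and is required")
  if (pssm@sequence != sp@sequence)
    dtiValidationError(sprintf(
      "sequence mismatch between PSSM and SPD profiles for '%s'/'%s'",
      pssm@proteinId, sp@proteinId))
  out <- pssmBigram(normalizePSSM(pssm, method = norm))
  if ("B" %in% groups)
    out <- c(out, ssComposition(sp), asaComposition(sp),
             taComposition(torsionTransform(sp)))
  if ("C" %in% groups) {
    t <- torsionTransform(sp)
    out <- c(out, taAutoCovariance(t, df), spAutoCovariance(sp, df))
  }
  if ("D" %in% groups) {
    t <- torsionTransform(sp)
    out <- c(out, taBigram(t), spBigram(sp))
  }
  out
}
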