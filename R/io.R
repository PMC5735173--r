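#' @include AllClasses.R
NULL

# detect comma vs tab delimiter from the first line of a text file
.detectSep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(",")
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

.isNumberToken <- function(x) grepl("^-?[0-9]+(\\.[0-9]+)?$", x)

# ---------------------------------------------------------------------------
# PSSM
# ---------------------------------------------------------------------------

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the layout written by `psiblast -out_ascii_pssm`: a short header,
#' one line per residue (position index, residue letter, then at least 20
#' integer score columns, possibly followed by 20 percentage columns and
#' per-row statistics), and trailing statistics lines. Only the first 20
#' numeric columns of each residue line are retained, regardless of how
#' many the dialect carries; the sequence is reconstructed from the residue
#' column.
#'
#' @param path path to the PSSM file.
#' @param proteinId identifier to attach; defaults to the file base name.
#' @return a [PSSMProfile-class] object.
#' @examples
#' f <- tempfile(fileext = ".pssm")
#' makePSSM(length = 6, seed = 1, path = f)
#' readPSSM(f)
#' @export
readPSSM <- function(path, proteinId = NULL) {
  if (!file.exists(path)) dtiParseError(paste0("no such file: ", path))
  if (is.null(proteinId))
    proteinId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  # residue lines: 1-based index, residue letter, then numbers
  isRes <- grepl("^\\s*[0-9]+\\s+[A-Za-z](\\s|$)", lines)
  if (!any(isRes))
    dtiParseError(paste0(path, ": no residue lines found"))
  idx <- which(isRes)
  scores <- matrix(0, nrow = length(idx), ncol = 20L)
  residues <- character(length(idx))
  for (r in seq_along(idx)) {
    ln <- idx[r]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    residues[r] <- tok[2L]
    rest <- tok[-(1:2)]
    if (length(rest) < 20L)
      dtiParseError(sprintf(
        "%s: line %d has %d score columns, expected at least 20",
        path, ln, length(rest)))
    vals <- rest[1:20]
    if (!all(.isNumberToken(vals)))
      dtiParseError(sprintf("%s: non-numeric score on line %d", path, ln))
    num <- as.numeric(vals)
    if (any(num != round(num)))
      dtiParseError(sprintf("%s: non-integer score on line %d", path, ln))
    scores[r, ] <- num
  }
  if (length(residues) < 2L)
    dtiParseError(paste0(path, ": fewer than 2 residue lines"))
  PSSMProfile(proteinId, paste(residues, collapse = ""), scores)
}

#' Write a PSSMProfile as a PSI-BLAST-style ASCII file
#'
#' Emits the 40-column dialect (scores followed by weighted observed
#' percentages, here zeros) plus the usual trailing per-row columns, so the
#' file exercises the "keep the first 20 numeric columns" contract of
#' [readPSSM()].
#'
#' @param profile a [PSSMProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePSSM <- function(profile, path) {
  stopifnot(is(profile, "PSSMProfile"))
  sq <- strsplit(profile@sequence, "")[[1]]
  sc <- profile@scores
  hdr <- c("",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapped matches"),
    paste0("            ",
           paste(sprintf("%3s", c(PSSM_ALPHABET, PSSM_ALPHABET)),
                 collapse = " ")))
  body <- vapply(seq_along(sq), function(i) {
    paste0(sprintf("%5d %s ", i, sq[i]),
           paste(sprintf("%3d", as.integer(sc[i, ])), collapse = " "),
           " ",
           paste(sprintf("%3d", integer(20)), collapse = " "),
           sprintf("  %4.2f %8.2f", 0, 0))
  }, character(1))
  tail <- c("", "                      K         Lambda",
            "Standard Ungapped    0.1000     0.3000")
  writeLines(c(hdr, body, tail), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SPD (SPIDER2)
# ---------------------------------------------------------------------------

#' Read a SPIDER2 SPD structural profile
#'
#' Expects the SPIDER2 column layout: a `#` header line, then one line per
#' residue with columns index, AA, SS, ASA, phi, psi, theta, tau, P(C),
#' P(E), P(H). Secondary-structure labels are validated against
#' `{C, E, H}`; probability rows deviating from sum 1 by more than 1e-2 are
#' rejected, smaller deviations are renormalized.
#'
#' @param path path to the SPD file.
#' @param proteinId identifier; defaults to the file base name.
#' @return a [StructuralProfile-class] object.
#' @export
readSPD <- function(path, proteinId = NULL) {
  if (!file.exists(path)) dtiParseError(paste0("no such file: ", path))
  if (is.null(proteinId))
    proteinId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) dtiParseError(paste0(path, ": no residue lines"))
  L <- length(rows)
  residues <- character(L); ss <- character(L); asa <- numeric(L)
  angles <- matrix(0, L, 4L); probs <- matrix(0, L, 3L)
  for (r in seq_len(L)) {
    ln <- rows[r]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 11L)
      dtiParseError(sprintf("%s: line %d has %d columns, expected 11",
                            path, ln, length(tok)))
    residues[r] <- tok[2L]
    if (!(tok[3L] %in% SS_LABELS))
      dtiParseError(sprintf("%s: line %d: unknown SS label '%s'",
                            path, ln, tok[3L]))
    ss[r] <- tok[3L]
    num <- suppressWarnings(as.numeric(tok[4:11]))
    if (anyNA(num))
      dtiParseError(sprintf("%s: line %d: non-numeric field", path, ln))
    asa[r] <- num[1L]
    angles[r, ] <- num[2:5]
    p <- num[6:8]
    if (abs(sum(p) - 1) > 1e-2)
      dtiParseError(sprintf(
        "%s: line %d: structural probabilities sum to %.4f (> 1e-2 off 1)",
        path, ln, sum(p)))
    probs[r, ] <- p / sum(p)
  }
  StructuralProfile(proteinId, paste(residues, collapse = ""),
                    ss, asa, angles, probs)
}

#' Write a StructuralProfile in SPIDER2 SPD layout
#'
#' @param profile a [StructuralProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSPD <- function(profile, path) {
  stopifnot(is(profile, "StructuralProfile"))
  sq <- strsplit(profile@sequence, "")[[1]]
  hdr <- "# index AA SS ASA Phi Psi Theta(i-1=>i+1) Tau(i-2=>i+2) P(C) P(E) P(H)"
  body <- vapply(seq_along(sq), function(i) {
    paste(i, sq[i], profile@ss[i],
          sprintf("%.1f", profile@asa[i]),
          paste(sprintf("%.4f", profile@angles[i, ]), collapse = " "),
          paste(sprintf("%.6f", profile@probs[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Fingerprints
# ---------------------------------------------------------------------------

#' Read drug fingerprints from a CSV/TSV table
#'
#' Two columns: `drug_id` and `bits`. The `bits` field is either an
#' 881-character 0/1 string or a comma-separated list of set-bit indices
#' (0-based, < 881; quote the field in CSV). An empty bits field means an
#' all-zero fingerprint.
#'
#' @param path path to the table (delimiter auto-detected: tab or comma).
#' @return named list of [DrugFingerprint-class] objects (names = drug ids).
#' @export
readFingerprints <- function(path) {
  if (!file.exists(path)) dtiParseError(paste0("no such file: ", path))
  sep <- .detectSep(path)
  df <- tryCatch(
    read.table(path, sep = sep, header = TRUE, quote = "\"",
               colClasses = "character", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) dtiParseError(paste0(path, ": ", conditionMessage(e))))
  if (ncol(df) < 2L)
    dtiParseError(paste0(path, ": expected columns drug_id, bits"))
  ids <- df[[1L]]; field <- df[[2L]]
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- .parseFingerprintField(ids[i], field[i])
  }
  names(out) <- ids
  out
}

.parseFingerprintField <- function(id, field) {
  field <- trimws(field)
  bits <- integer(FP_LENGTH)
  if (grepl("^[01]+$", field) && !grepl(",", field)) {
    if (nchar(field) != FP_LENGTH)
      dtiValidationError(sprintf(
        "drug '%s': bit string has length %d, expected %d",
        id, nchar(field), FP_LENGTH))
    bits <- as.integer(strsplit(field, "")[[1]])
  } else if (nzchar(field)) {
    idx <- suppressWarnings(as.integer(strsplit(field, ",")[[1]]))
    if (anyNA(idx))
      dtiValidationError(sprintf("drug '%s': non-integer bit index", id))
    if (any(idx < 0L | idx >= FP_LENGTH))
      dtiValidationError(sprintf(
        "drug '%s': bit index out of range [0, %d)", id, FP_LENGTH))
    bits[idx + 1L] <- 1L
  }
  DrugFingerprint(id, bits)
}

#' Write fingerprints as a two-column CSV (dense 0/1 strings)
#'
#' @param fps named list of [DrugFingerprint-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFingerprints <- function(fps, path) {
  lines <- c("drug_id,bits",
             vapply(fps, function(fp)
               paste0(fp@drugId, ",", paste(fp@bits, collapse = "")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Interaction lists
# ---------------------------------------------------------------------------

#' Read a drug-target interaction list
#'
#' Two-column delimited file (drug id, target id); a header line is
#' detected by the presence of the words "drug" and "target". Duplicate
#' pairs are collapsed with a warning; row order is otherwise preserved.
#'
#' @param path path to the CSV/TSV file.
#' @return data.frame with columns `drugId`, `targetId`.
#' @export
readInteractions <- function(path) {
  if (!file.exists(path)) dtiParseError(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) dtiParseError(paste0(path, ": empty file"))
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  if (grepl("drug", lines[1L], ignore.case = TRUE) &&
      grepl("target", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  if (!length(lines)) dtiParseError(paste0(path, ": no interaction rows"))
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    dtiParseError(sprintf("%s: line %d has fewer than 2 columns",
                          path, bad[1L]))
  df <- data.frame(
    drugId = trimws(vapply(parts, `[[`, character(1), 1L)),
    targetId = trimws(vapply(parts, `[[`, character(1), 2L)),
    stringsAsFactors = FALSE)
  if (any(!nzchar(df$drugId)) || any(!nzchar(df$targetId)))
    dtiValidationError(paste0(path, ": empty id field"))
  key <- paste(df$drugId, df$targetId, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%s: %d duplicate interaction pair(s) collapsed",
                    path, sum(duplicated(key))))
    df <- df[!duplicated(key), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a pair feature matrix as CSV (plus JSON sidecar)
#'
#' Writes one row per pair with `drug_id`, `target_id`, `label` and all
#' named feature columns, and a `<path>.json` sidecar with the network
#' statistics.
#'
#' @param pfm a [PairFeatureMatrix-class].
#' @param path output CSV path.
#' @param sidecar list of extra metadata stored alongside (default empty).
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(pfm, path, sidecar = list()) {
  stopifnot(is(pfm, "PairFeatureMatrix"))
  df <- cbind(
    data.frame(drug_id = pfm@keys$drugId, target_id = pfm@keys$targetId,
               label = pfm@labels, stringsAsFactors = FALSE),
    as.data.frame(pfm@features, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  meta <- c(list(n_pairs = nrow(pfm@features),
                 n_features = ncol(pfm@features),
                 groups = paste(pfm@groups, collapse = ""),
                 n_positive = sum(pfm@labels == 1),
                 n_negative = sum(pfm@labels == -1)),
            sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
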