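#' @include AllClasses.R
NULL

#' Drug-side feature block (881 bits)
#'
#' Maps a fingerprint identically into the pair feature space, preserving
#' PubChem bit order (bit index 0..880, column names `fp_0` ... `fp_880`).
#'
#' @param fp a [DrugFingerprint-class].
#' @return named numeric vector of length 881 with values in \{0, 1\}.
#' @export
fingerprintBlock <- function(fp) {
  stopifnot(is(fp, "DrugFingerprint"))
  v <- as.numeric(fp@bits)
  names(v) <- paste0("fp_", 0:(FP_LENGTH - 1L))
  v
}

#' Compute a PubChem fingerprint from SMILES (optional adapter)
#'
#' Non-core adapter around the rcdk toolkit's PubChem 881-key substructure
#' fingerprinter. Fingerprints produced here may differ bit-for-bit from
#' other toolkits; the core package treats fingerprints strictly as inputs
#' and never requires this function. It errors informatively when rcdk is
#' not installed.
#'
#' @param smiles a single SMILES string.
#' @param drugId identifier for the resulting fingerprint.
#' @return a [DrugFingerprint-class].
#' @export
smilesToFingerprint <- function(smiles, drugId = "drug") {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    dtiValidationError("smiles must be a single non-empty string")
  if (!requireNamespace("rcdk", quietly = TRUE))
    stop(errorCondition(
      paste("smilesToFingerprint requires the optional 'rcdk' package;",
            "install it or supply precomputed fingerprints via",
            "readFingerprints()"),
      class = c("dtiUnavailableFeature", "dtiError")))
  mol <- tryCatch(rcdk::parse.smiles(smiles)[[1L]], error = function(e) NULL)
  if (is.null(mol))
    dtiParseError(sprintf("unparsable SMILES: '%s'", smiles))
  fp <- rcdk::get.fingerprint(mol, type = "pubchem")
  bits <- integer(FP_LENGTH)
  bits[fp@bits] <- 1L
  DrugFingerprint(drugId, bits)
}
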