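## Amino-acid alphabet and small shared helpers.

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Fixed, alphabetical one-letter codes. Column order of every emission
#' matrix and background vector.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")

## split a sequence string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Uniform amino-acid background distribution
#' @return named numeric vector of length 20 summing to 1.
#' @export
uniform_background <- function() {
  setNames(rep(1 / 20, 20), AA_ALPHABET)
}

## Map residues to 0-based alphabet indices for the C++ core.
## X -> -1 (background wildcard); anything else is an alphabet error.
encode_protein <- function(protein, context = "sequence") {
  cc <- chars(toupper(protein))
  idx <- match(cc, AA_ALPHABET)
  wild <- cc == "X"
  bad <- is.na(idx) & !wild
  if (any(bad)) {
    stop(sprintf("alphabet error: %s contains non-amino-acid symbol '%s' at position %d",
                 context, cc[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  out <- idx - 1L
  out[wild] <- -1L
  out
}

## validate a gapped alignment row; returns uppercase characters
check_aligned_row <- function(row, row_id, row_index) {
  cc <- chars(toupper(row))
  ok <- cc %in% c(AA_ALPHABET, "-", ".")
  if (!all(ok)) {
    j <- which(!ok)[1]
    stop(sprintf("alphabet error: row '%s' (row %d) has non-amino-acid symbol '%s' at column %d",
                 row_id, row_index, cc[j], j), call. = FALSE)
  }
  cc[cc == "."] <- "-"
  cc
}

fmt_pct <- function(x) round(100 * x, 1)
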