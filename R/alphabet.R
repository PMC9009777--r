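# Amino-acid alphabet, in the conventional ARNDCQEGHILKMFPSTWYV order used by
# the empirical substitution models.  Gaps ('-', '.') and unknowns ('X') are
# treated as missing throughout and never enter frequency counts.

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP_CHARS <- c("-", ".")

#' Encode amino-acid characters as integer codes
#'
#' Maps the 20 standard amino acids to 1..20 (ARNDCQEGHILKMFPSTWYV order);
#' gaps and 'X' become `NA`.
#'
#' @param x character vector of single residues (any case).
#' @return integer vector of the same length.
#' @keywords internal
aa_encode <- function(x) {
  m <- match(toupper(x), AA_LETTERS)
  m[toupper(x) %in% c(GAP_CHARS, "X")] <- NA_integer_
  m
}

# Residues allowed in an alignment besides the 20 amino acids.
ALLOWED_CHARS <- c(AA_LETTERS, GAP_CHARS, "X")
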