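# Genotype call alphabet and integer coding shared across the package.
#
# Calls are case-sensitive and exactly {A, B, H, -}: A and B the two parental
# homozygotes, H the heterozygote, "-" a missing call.  The integer coding
# (A=1, B=2, H=3, -=4) underlies the vectorised scoring engine.

CALL_LEVELS <- c("A", "B", "H", "-")
CALL_MISSING <- "-"

#' Genotype call alphabet
#'
#' The four admissible genotype call symbols: `"A"` and `"B"` for the two
#' parental homozygotes, `"H"` for the heterozygote and `"-"` for a missing
#' call.  Calls are case-sensitive; no other symbol (e.g. `"N"` or lowercase)
#' is accepted anywhere in the package.
#'
#' @return A character vector of length four.
#' @examples
#' genotype_calls()
#' @export
genotype_calls <- function() CALL_LEVELS

# Map a character vector of calls to integer codes 1..4, erroring on any
# symbol outside the alphabet.  `what` labels the offending context.
encode_calls <- function(x, what = "call") {
  codes <- match(x, CALL_LEVELS)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    abort(sprintf(
      "invalid %s %s at position %d: calls must be one of %s (case-sensitive)",
      what, encodeString(x[bad], quote = "'"), bad,
      paste0("'", CALL_LEVELS, "'", collapse = ", ")
    ))
  }
  codes
}

# Extract the individuals x markers character matrix from a genotype tibble
# (first column = individual ids, remaining columns = marker calls).
geno_matrix <- function(geno) {
  stopifnot(is.data.frame(geno), ncol(geno) >= 2L)
  m <- as.matrix(geno[, -1L, drop = FALSE])
  storage.mode(m) <- "character"
  rownames(m) <- as.character(geno[[1L]])
  m
}

# Integer-coded genotype matrix (A=1, B=2, H=3, -=4) with dimnames kept.
geno_codes <- function(geno) {
  m <- geno_matrix(geno)
  codes <- match(m, CALL_LEVELS)
  if (anyNA(codes)) {
    idx <- which(is.na(codes))[1L]
    rc <- arrayInd(idx, dim(m))
    abort(sprintf(
      "invalid genotype call '%s' for individual '%s' at marker '%s'",
      m[idx], rownames(m)[rc[1L]], colnames(m)[rc[2L]]
    ))
  }
  matrix(codes, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
}
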