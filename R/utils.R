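#' Round half away from zero
#'
#' Report-style rounding: ties go away from zero (so 12.5 -> 13), unlike
#' [base::round()], which rounds half to even. Used for all human-readable
#' percentages in summary tables.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_away(12.5) # 13, not 12
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# validate that strings contain only unambiguous nucleotides (plus N)
.check_nucleotides <- function(x, ids = NULL, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    label <- if (!is.null(ids)) paste(ids[bad], collapse = ", ") else
      paste(which(bad), collapse = ", ")
    stop("non-nucleotide characters in ", what, ": ", label, call. = FALSE)
  }
  invisible(TRUE)
}

# split a string vector into a character matrix, one column per position
.char_matrix <- function(x, width) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0, ncol = width))
  m <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
              ncol = width, byrow = TRUE)
  m
}
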