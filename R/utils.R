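#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. Uses the
#' IUPAC-aware machinery in Biostrings, so `N` is preserved.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
rev_comp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- rep(NA_character_, length(x))
  nz <- !is.na(x) & nzchar(x)
  out[!nz & !is.na(x)] <- ""
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nz])))
  }
  out
}

#' Random DNA sequence
#'
#' @param len sequence length in nt.
#' @param gc GC content (fraction).
#' @return a single DNA string.
#' @export
random_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Round half away from zero
#'
#' Fixed-point rounding where ties go away from zero (the convention used in
#' the summary-table percentages), unlike base `round()`'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# All start positions (0-based) of `pattern` in `subject`, overlaps included,
# mismatches up to max_mismatch (substitutions only). N never matches.
match_starts0 <- function(pattern, subject, max_mismatch = 0L) {
  if (nchar(pattern) > nchar(subject)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  BiocGenerics::start(m) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
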