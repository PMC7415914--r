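#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T/N;
#' case-insensitive, returned uppercase).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  chartr("ACGTN", "TGCAN", stri_reverse_upper(x))
}

stri_reverse_upper <- function(x) stringi::stri_reverse(toupper(x))

# canonical form of a k-mer set: lexicographic min of sequence and its
# reverse complement (odd k => never palindromic)
canonical <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stage-tagged error for pipeline diagnostics
abort_stage <- function(msg, stage) {
  rlang::abort(paste0("[", stage, "] ", msg))
}
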