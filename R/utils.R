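#' Truncate a percentage to a fixed number of decimals
#'
#' Genome-description tables in this field conventionally truncate (not
#' round) percentages: 135 of 2,003 genes prints as 6.73, not 6.74. A small
#' epsilon guards against binary floating-point representations of exact
#' decimal values being floored one unit low.
#'
#' @param x numeric vector of percentages.
#' @param digits decimals kept (default 2).
#' @return truncated numeric vector.
#' @examples
#' trunc_percent(100 * 135 / 2003) # 6.73
#' @export
trunc_percent <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 1e-9) / f
}

fmt_percent <- function(x, digits = 2) {
  formatC(trunc_percent(x, digits), format = "f", digits = digits)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A, C, G, T, N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
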