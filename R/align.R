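# Pairwise alignment: scoring schemes and the Needleman-Wunsch /
# Smith-Waterman front ends over the compiled Gotoh kernel.

.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- as.matrix(e$BLOSUM62)
  }
  .pkg_cache$BLOSUM62
}

#' Alignment scoring scheme
#'
#' Bundles the substitution scores and affine gap costs used by
#' [needleman_wunsch()] and [smith_waterman()]. A gap run of length L costs
#' `gap_open + L * gap_extend`. For nucleotides the default is the
#' BLAST-like match +5 / mismatch -4, gap open 10, gap extend 0.5; `N`
#' scores as a mismatch against every base, including `N` itself, so
#' ambiguous draft-genome positions never inflate a score. For proteins the
#' default is BLOSUM62 with gap open 11 / extend 1.
#'
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param match,mismatch scores used when `matrix` is `NULL` (nucleotide
#'   schemes); `match` must exceed `mismatch`.
#' @param matrix optional named substitution matrix (rows/columns labelled
#'   by residue); defaults to BLOSUM62 for protein schemes.
#' @param gap_open,gap_extend non-negative gap costs, `gap_extend <=
#'   gap_open`.
#' @return an object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()                      # nucleotide defaults
#' scoring_scheme("protein")             # BLOSUM62 defaults
#' @export
scoring_scheme <- function(alphabet = c("nucleotide", "protein"),
                           match = NULL, mismatch = NULL, matrix = NULL,
                           gap_open = NULL, gap_extend = NULL) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nucleotide") {
    match <- match %||% 5
    mismatch <- mismatch %||% -4
    gap_open <- gap_open %||% 10
    gap_extend <- gap_extend %||% 0.5
    if (is.null(matrix)) {
      chars <- c("A", "C", "G", "T", "N")
      matrix <- base::matrix(mismatch, 5, 5, dimnames = list(chars, chars))
      diag(matrix) <- match
      matrix["N", "N"] <- mismatch  # N is never a match, even to N
    }
    if (!(match > mismatch)) stop("match score must exceed mismatch score")
  } else {
    gap_open <- gap_open %||% 11
    gap_extend <- gap_extend %||% 1
    if (is.null(matrix)) matrix <- .blosum62()
  }
  if (gap_open < 0 || gap_extend < 0) stop("gap costs must be non-negative")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  if (is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must have identical row and column names")
  structure(
    list(alphabet = alphabet, match = match, mismatch = mismatch,
         matrix = matrix, chars = paste(rownames(matrix), collapse = ""),
         gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Scoring scheme (", x$alphabet, ")\n", sep = "")
  if (!is.null(x$match))
    cat("  match ", x$match, ", mismatch ", x$mismatch, "\n", sep = "")
  else
    cat("  substitution matrix over {", x$chars, "}\n", sep = "")
  cat("  gap open ", x$gap_open, ", gap extend ", x$gap_extend,
      " (run of L costs open + L*extend)\n", sep = "")
  invisible(x)
}

.check_seq <- function(x, scheme, what) {
  if (!.is_string(x) || nchar(x) == 0L)
    stop("sequence '", what, "' must be a single non-empty string")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), rownames(scheme$matrix))
  if (length(bad))
    stop("sequence '", what, "' contains characters outside the scoring ",
         "alphabet: ", paste(bad, collapse = ", "),
         " (mixed alphabets or unsupported ambiguity codes?)")
  invisible(TRUE)
}

.alignment_result <- function(raw, scheme, type) {
  ca <- strsplit(raw$aligned_a, "")[[1]]
  cb <- strsplit(raw$aligned_b, "")[[1]]
  n_columns <- length(ca)
  gap <- ca == "-" | cb == "-"
  n_match <- sum(!gap & ca == cb)
  res <- list(
    aligned_a = raw$aligned_a, aligned_b = raw$aligned_b,
    score = raw$score, n_match = n_match, n_columns = n_columns,
    n_gap_columns = sum(gap),
    identity_percent = if (n_columns) 100 * n_match / n_columns else NA_real_,
    type = type, scheme = scheme
  )
  if (type == "local")
    res[c("start_a", "end_a", "start_b", "end_b")] <-
      raw[c("start_a", "end_a", "start_b", "end_b")]
  class(res) <- "pairwise_alignment"
  res
}

.align <- function(a, b, scheme, type) {
  .check_seq(a, scheme, "a")
  .check_seq(b, scheme, "b")
  code <- c(global = 0L, local = 1L, semiglobal = 2L)[[type]]
  raw <- align_pair_cpp(a, b, scheme$matrix, scheme$chars,
                        scheme$gap_open, scheme$gap_extend, code)
  .alignment_result(raw, scheme, type)
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' End-to-end alignment under affine gap costs (Gotoh recurrence). Terminal
#' gaps are penalized; set `type = "semiglobal"` for free terminal gaps.
#' The traceback is deterministic: ties resolve diagonal, then up (gap in
#' `b`), then left (gap in `a`).
#'
#' @param a,b sequences (single strings) over the scheme's alphabet.
#' @param scheme a [scoring_scheme()].
#' @param type `"global"` (default) or `"semiglobal"`.
#' @return a `pairwise_alignment` with the gapped strings, the optimal
#'   `score`, match/column/gap-column counts and `identity_percent`
#'   (all-columns definition; see [percent_identity()] for alternatives).
#' @examples
#' aln <- needleman_wunsch("ACGT", "ACGT")
#' aln$identity_percent  # 100
#' @seealso [smith_waterman()], [percent_identity()]
#' @export
needleman_wunsch <- function(a, b, scheme = scoring_scheme(),
                             type = c("global", "semiglobal")) {
  type <- match.arg(type)
  .align(a, b, scheme, type)
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' Best-scoring local alignment under affine gap costs. The empty alignment
#' is allowed, so the score is never negative; the coordinates of the
#' aligned region (1-based, inclusive) are reported in `start_a`/`end_a`
#' and `start_b`/`end_b` (0 for an empty alignment).
#'
#' @inheritParams needleman_wunsch
#' @return a `pairwise_alignment` (see [needleman_wunsch()]).
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  .align(a, b, scheme, "local")
}

#' Percent identity of a pairwise alignment
#'
#' The denominator is a modelling choice and materially changes reported
#' identities on gapped alignments:
#' `all_columns` divides matches by every alignment column (default),
#' `ungapped_columns` excludes gap columns from the denominator, and
#' `shorter_seq` divides by the length of the shorter input sequence.
#'
#' @param aln a `pairwise_alignment`.
#' @param mode denominator convention.
#' @return identity as a percentage in \[0, 100\].
#' @export
percent_identity <- function(aln, mode = c("all_columns", "ungapped_columns",
                                           "shorter_seq")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (aln$n_columns == 0L)
    stop("percent identity is undefined for a zero-length alignment")
  denom <- switch(mode,
    all_columns = aln$n_columns,
    ungapped_columns = aln$n_columns - aln$n_gap_columns,
    shorter_seq = min(nchar(gsub("-", "", aln$aligned_a, fixed = TRUE)),
                      nchar(gsub("-", "", aln$aligned_b, fixed = TRUE)))
  )
  if (denom == 0L)
    stop("percent identity is undefined: empty denominator under mode '",
         mode, "'")
  100 * aln$n_match / denom
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("%s alignment: score %.2f, %d columns, %d matches (%.2f%%)\n",
              x$type, x$score, x$n_columns, x$n_match, x$identity_percent))
  if (x$n_columns == 0L) return(invisible(x))
  starts <- seq(1, x$n_columns, by = width)
  ca <- strsplit(x$aligned_a, "")[[1]]
  cb <- strsplit(x$aligned_b, "")[[1]]
  for (s in starts) {
    e <- min(s + width - 1L, x$n_columns)
    mid <- ifelse(ca[s:e] == cb[s:e] & ca[s:e] != "-", "|", " ")
    cat(paste(ca[s:e], collapse = ""), "\n",
        paste(mid, collapse = ""), "\n",
        paste(cb[s:e], collapse = ""), "\n\n", sep = "")
  }
  invisible(x)
}

#' Write a pairwise alignment as aligned FASTA
#'
#' @param aln a `pairwise_alignment`.
#' @param path output file.
#' @param ids character vector of length 2 with record names.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path, ids = c("a", "b")) {
  stopifnot(inherits(aln, "pairwise_alignment"), length(ids) == 2L)
  writeLines(c(paste0(">", ids[1]), aln$aligned_a,
               paste0(">", ids[2]), aln$aligned_b), path)
  invisible(path)
}
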