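# 16S rRNA identity and the species-delineation decision rule.
#
# The conventional threshold is 98.7% 16S identity: a query whose best
# match falls strictly below it is a candidate new species (equal-to-
# threshold is NOT novel).

#' Pairwise 16S rRNA identity
#'
#' Globally aligns two 16S sequences and returns the percent identity.
#' Deposited 16S sequences vary in orientation, so by default both strands
#' of `b` are tried and the higher identity kept.
#'
#' @param a,b nucleotide sequences (single strings).
#' @param scheme nucleotide [scoring_scheme()].
#' @param mode identity denominator, see [percent_identity()].
#' @param both_strands try `b` and its reverse complement (default TRUE).
#' @return identity percentage (full precision; report rounded to 1
#'   decimal by convention).
#' @export
identity_16s <- function(a, b, scheme = scoring_scheme("nucleotide"),
                         mode = "all_columns", both_strands = TRUE) {
  fwd <- percent_identity(needleman_wunsch(a, b, scheme), mode)
  if (!both_strands) return(fwd)
  rev <- percent_identity(needleman_wunsch(a, revcomp(b), scheme), mode)
  max(fwd, rev)
}

#' Best 16S match and species-delineation verdict
#'
#' Ranks the references by identity to the query (descending; ties broken
#' by reference id for determinism) and applies the threshold rule to the
#' top hit: identity strictly below `threshold` gives
#' `"candidate_new_species"`, otherwise `"same_species_range"`.
#'
#' @param query 16S sequence (single string).
#' @param references named character vector of reference 16S sequences.
#' @param threshold species-delineation threshold (percent, default 98.7).
#' @inheritParams identity_16s
#' @return an `rrna_match`: `ranking` data frame (`subject_id`,
#'   `identity_percent`, ordered), `top_identity`, `threshold`, `verdict`.
#' @export
best_match_16s <- function(query, references, threshold = 98.7,
                           scheme = scoring_scheme("nucleotide"),
                           mode = "all_columns", both_strands = TRUE) {
  if (length(references) == 0L) stop("empty reference set")
  if (is.null(names(references)) || anyDuplicated(names(references)))
    stop("references must carry unique names")
  ids <- vapply(references, function(r)
    identity_16s(query, r, scheme, mode, both_strands), numeric(1))
  ord <- order(-ids, names(references))
  ranking <- data.frame(subject_id = names(references)[ord],
                        identity_percent = unname(ids[ord]),
                        stringsAsFactors = FALSE)
  top <- ranking$identity_percent[1]
  verdict <- if (top < threshold) "candidate_new_species"
             else "same_species_range"
  structure(list(ranking = ranking, top_identity = top,
                 top_subject = ranking$subject_id[1],
                 threshold = threshold, verdict = verdict),
            class = "rrna_match")
}

#' @export
print.rrna_match <- function(x, ...) {
  cat("16S rRNA best match: ", x$top_subject, " at ",
      sprintf("%.1f", x$top_identity), "% identity\n",
      "threshold ", x$threshold, "% -> ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Write a 16S ranking with verdicts as TSV
#'
#' Each reference gets the verdict its own identity would imply under the
#' threshold rule.
#'
#' @param x an `rrna_match`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rrna_tsv <- function(x, path) {
  stopifnot(inherits(x, "rrna_match"))
  df <- x$ranking
  df$identity_percent <- sprintf("%.1f", df$identity_percent)
  df$verdict <- ifelse(x$ranking$identity_percent < x$threshold,
                       "candidate_new_species", "same_species_range")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
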