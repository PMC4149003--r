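# Reciprocal-best-hit orthology over protein sequences.
#
# All-vs-all alignment is made desk-feasible by a shared k-mer prefilter
# (default: >= 2 shared 5-mers) standing in for BLAST-style seeding;
# candidate pairs are then scored by Smith-Waterman.

.ortho_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

.default_min_score <- function(scheme, n_residues = 25) {
  # score of an n-residue exact match under the scheme: for matrix schemes,
  # use the mean diagonal score as the per-residue self-match value
  per <- if (!is.null(scheme$match)) scheme$match
         else mean(diag(scheme$matrix)[rownames(scheme$matrix) != "*"])
  n_residues * per
}

#' Ortholog-search parameters
#'
#' Proteinortho-like defaults: minimum identity 25%, minimum coverage 50%
#' of the shorter protein, minimum alignment score equivalent to a
#' 25-residue exact match, and a shared-5-mer prefilter requiring at least
#' 2 shared k-mers before a pair is aligned.
#'
#' @param k k-mer size for the prefilter.
#' @param min_shared_kmers minimum shared k-mers for a candidate pair.
#' @param min_identity minimum local-alignment identity percent.
#' @param min_coverage minimum aligned fraction (percent) of the shorter
#'   protein.
#' @param min_score minimum alignment score (`NULL` = 25-residue match
#'   equivalent under the scheme).
#' @param scheme protein [scoring_scheme()].
#' @return an `ortho_params` list.
#' @export
ortho_params <- function(k = 5, min_shared_kmers = 2, min_identity = 25,
                         min_coverage = 50, min_score = NULL,
                         scheme = scoring_scheme("protein")) {
  stopifnot(k >= 1, min_shared_kmers >= 1)
  structure(list(k = as.integer(k),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 min_identity = min_identity, min_coverage = min_coverage,
                 min_score = min_score %||% .default_min_score(scheme),
                 scheme = scheme),
            class = "ortho_params")
}

.check_proteins <- function(x, what) {
  if (length(x) == 0L) return(invisible(TRUE))
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("protein set '", what, "' must carry unique names")
  invisible(TRUE)
}

#' Candidate similarity hits between two protein sets
#'
#' Pairs sharing at least `min_shared_kmers` k-mers are aligned with
#' [smith_waterman()]; hits below the score, identity or coverage
#' thresholds are dropped. Coverage is the fraction of the shorter
#' protein's residues present in the local alignment.
#'
#' @param proteins_a,proteins_b named character vectors of protein
#'   sequences (no internal stops).
#' @param params an [ortho_params()].
#' @return data frame of hits: `query_id`, `subject_id`, `score`,
#'   `identity_percent`, `coverage_percent`.
#' @export
candidate_hits <- function(proteins_a, proteins_b, params = ortho_params()) {
  stopifnot(inherits(params, "ortho_params"))
  .check_proteins(proteins_a, "a")
  .check_proteins(proteins_b, "b")
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), identity_percent = numeric(0),
                      coverage_percent = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(proteins_a) == 0L || length(proteins_b) == 0L) {
    warning("empty protein set: no hits")
    return(empty)
  }
  k <- params$k
  short_a <- nchar(proteins_a) < k
  short_b <- nchar(proteins_b) < k
  if (any(short_a) || any(short_b))
    warning("skipping protein(s) shorter than k = ", k, ": ",
            paste(c(names(proteins_a)[short_a], names(proteins_b)[short_b]),
                  collapse = ", "))
  proteins_a <- proteins_a[!short_a]
  proteins_b <- proteins_b[!short_b]
  if (length(proteins_a) == 0L || length(proteins_b) == 0L) return(empty)

  kb <- lapply(proteins_b, .ortho_kmers, k = k)
  index <- split(rep(names(kb), lengths(kb)), unlist(kb, use.names = FALSE))
  rows <- vector("list", length(proteins_a))
  for (qi in seq_along(proteins_a)) {
    q <- names(proteins_a)[qi]
    counts <- table(unlist(index[.ortho_kmers(proteins_a[[qi]], k)],
                           use.names = FALSE))
    cands <- names(counts)[counts >= params$min_shared_kmers]
    if (!length(cands)) next
    hits <- lapply(cands, function(s) {
      aln <- smith_waterman(proteins_a[[qi]], proteins_b[[s]], params$scheme)
      if (aln$n_columns == 0L) return(NULL)
      shorter <- min(nchar(proteins_a[[qi]]), nchar(proteins_b[[s]]))
      aligned_short <- min(
        nchar(gsub("-", "", aln$aligned_a, fixed = TRUE)),
        nchar(gsub("-", "", aln$aligned_b, fixed = TRUE)))
      cov <- 100 * aligned_short / shorter
      if (aln$score < params$min_score ||
          aln$identity_percent < params$min_identity ||
          cov < params$min_coverage) return(NULL)
      data.frame(query_id = q, subject_id = s, score = aln$score,
                 identity_percent = aln$identity_percent,
                 coverage_percent = cov, stringsAsFactors = FALSE)
    })
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (length(hits)) rows[[qi]] <- do.call(rbind, hits)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Best subject per query
#'
#' Ties on score are broken by higher identity, then by the
#' lexicographically smaller subject id, so results are deterministic.
#'
#' @param hits data frame from [candidate_hits()] (one directed
#'   comparison).
#' @return data frame with one row per query that has a surviving hit.
#' @export
best_hit_table <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, -hits$score, -hits$identity_percent,
               hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two protein sets
#'
#' A pair (x, y) is an ortholog pair iff y is x's best hit in B and x is
#' y's best hit in A. Because the local-alignment score is symmetric, one
#' undirected hit search feeds both directions. The mapping is one-to-one.
#'
#' @inheritParams candidate_hits
#' @param genome_a_id,genome_b_id labels carried in the result.
#' @return an `ortholog_map`: data frame with `gene_a`, `gene_b` plus the
#'   per-pair local score/identity, and attributes `genome_a_id`,
#'   `genome_b_id`.
#' @export
reciprocal_best_hits <- function(proteins_a, proteins_b,
                                 params = ortho_params(),
                                 genome_a_id = "A", genome_b_id = "B") {
  hits <- candidate_hits(proteins_a, proteins_b, params)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), identity_percent = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    out <- empty
  } else {
    ab <- best_hit_table(hits)
    rev_hits <- data.frame(query_id = hits$subject_id,
                           subject_id = hits$query_id, score = hits$score,
                           identity_percent = hits$identity_percent,
                           coverage_percent = hits$coverage_percent,
                           stringsAsFactors = FALSE)
    ba <- best_hit_table(rev_hits)
    back <- setNames(ba$subject_id, ba$query_id)
    keep <- !is.na(back[ab$subject_id]) & back[ab$subject_id] == ab$query_id
    out <- data.frame(gene_a = ab$query_id[keep], gene_b = ab$subject_id[keep],
                      score = ab$score[keep],
                      identity_percent = ab$identity_percent[keep],
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_a), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, genome_a_id = genome_a_id, genome_b_id = genome_b_id,
            class = c("ortholog_map", "data.frame"))
}

#' Write hits or an ortholog map as TSV
#' @param x data frame (hits or `ortholog_map`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
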