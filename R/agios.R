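# AGIOS: average genomic identity of orthologous gene sequences.
#
# The two-alphabet flow is deliberate and mirrors the method's definition:
# orthologs are detected on PROTEIN sequences (reciprocal best hits), then
# the corresponding NUCLEOTIDE gene sequences are globally aligned and the
# per-pair percent identities averaged.

.gene_proteins <- function(genes, include_flagged) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "nt_seq", "aa_seq") %in% names(genes)))
  keep <- if (include_flagged || is.null(genes$valid)) rep(TRUE, nrow(genes))
          else genes$valid
  g <- genes[keep, , drop = FALSE]
  list(aa = setNames(gsub("*", "", g$aa_seq, fixed = TRUE), g$gene_id),
       nt = setNames(g$nt_seq, g$gene_id))
}

#' AGIOS for one genome pair
#'
#' Detects orthologs between the two gene sets by reciprocal best hits on
#' protein sequences, globally aligns the nucleotide sequence of each
#' ortholog pair with [needleman_wunsch()], and reports the unweighted
#' arithmetic mean of the per-pair percent identities.
#'
#' @param genes_a,genes_b `gene_table` data frames (from [extract_genes()]
#'   or [generate_ancestor()]/[evolve_genome()]) carrying both `nt_seq` and
#'   `aa_seq`.
#' @param params [ortho_params()] for the protein RBH stage.
#' @param scheme nucleotide [scoring_scheme()] for the identity stage.
#' @param identity_mode denominator convention, see [percent_identity()].
#' @param length_weighted average per-pair identities weighted by
#'   alignment length instead of the default unweighted mean.
#' @param include_flagged include genes flagged as frameshifted or
#'   containing internal stops (excluded by default).
#' @return an `agios_pair` object: genome ids, `n_orthologs`,
#'   `per_pair_identities`, `mean_identity_percent` (`NA` with a flag when
#'   there are no orthologs) and the ortholog map.
#' @examples
#' \donttest{
#' anc <- generate_ancestor(n_genes = 12, mean_gene_length = 300,
#'                          gc_target = 0.5, seed = 1)
#' agios_pair(anc$genes, anc$genes)$mean_identity_percent  # 100
#' }
#' @export
agios_pair <- function(genes_a, genes_b, params = ortho_params(),
                       scheme = scoring_scheme("nucleotide"),
                       identity_mode = "all_columns",
                       length_weighted = FALSE, include_flagged = FALSE) {
  pa <- .gene_proteins(genes_a, include_flagged)
  pb <- .gene_proteins(genes_b, include_flagged)
  ga_id <- if (!is.null(genes_a$genome_id) && nrow(genes_a))
    genes_a$genome_id[1] else "A"
  gb_id <- if (!is.null(genes_b$genome_id) && nrow(genes_b))
    genes_b$genome_id[1] else "B"
  om <- reciprocal_best_hits(pa$aa, pb$aa, params,
                             genome_a_id = ga_id, genome_b_id = gb_id)
  n <- nrow(om)
  ids <- numeric(n)
  wts <- numeric(n)
  for (i in seq_len(n)) {
    aln <- needleman_wunsch(pa$nt[[om$gene_a[i]]], pb$nt[[om$gene_b[i]]],
                            scheme)
    ids[i] <- percent_identity(aln, identity_mode)
    wts[i] <- aln$n_columns
  }
  mean_id <- if (n == 0L) NA_real_
             else if (length_weighted) sum(ids * wts) / sum(wts)
             else mean(ids)
  structure(
    list(genome_a_id = ga_id, genome_b_id = gb_id, n_orthologs = n,
         per_pair_identities = ids, mean_identity_percent = mean_id,
         no_orthologs = n == 0L, identity_mode = identity_mode,
         ortholog_map = om),
    class = "agios_pair"
  )
}

#' @export
print.agios_pair <- function(x, ...) {
  cat("AGIOS ", x$genome_a_id, " vs ", x$genome_b_id, ": ", sep = "")
  if (x$no_orthologs) {
    cat("no orthologs detected; mean identity undefined\n")
  } else {
    cat(x$n_orthologs, " orthologous gene pairs, mean nucleotide identity ",
        fmt_percent(x$mean_identity_percent), "%\n", sep = "")
  }
  invisible(x)
}

#' AGIOS matrix over a set of genomes
#'
#' Computes every unordered genome pair once and arranges the results the
#' way genome-description papers print them: protein-coding gene counts on
#' the diagonal, shared ortholog counts in the lower triangle, AGIOS
#' percentages (truncated to 2 decimals on output) in the upper triangle.
#'
#' @param gene_tables named list of `gene_table` data frames; names are the
#'   genome ids (must be unique).
#' @inheritParams agios_pair
#' @return an `agios_matrix` object with `genome_ids`, `gene_counts`,
#'   `n_orthologs` (matrix), `agios` (matrix) and the list of pair results.
#' @export
agios_matrix <- function(gene_tables, params = ortho_params(),
                         scheme = scoring_scheme("nucleotide"),
                         identity_mode = "all_columns",
                         include_flagged = FALSE) {
  stopifnot(is.list(gene_tables), length(gene_tables) >= 2)
  ids <- names(gene_tables)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("gene_tables must be a named list with unique genome ids")
  k <- length(ids)
  counts <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  agios <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  gene_counts <- vapply(gene_tables, function(g) {
    if (include_flagged || is.null(g$valid)) nrow(g) else sum(g$valid)
  }, numeric(1))
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    pr <- agios_pair(gene_tables[[i]], gene_tables[[j]], params, scheme,
                     identity_mode, include_flagged = include_flagged)
    pairs[[paste(ids[i], ids[j], sep = "|")]] <- pr
    counts[i, j] <- counts[j, i] <- pr$n_orthologs
    agios[i, j] <- agios[j, i] <- pr$mean_identity_percent
  }
  structure(list(genome_ids = ids, gene_counts = gene_counts,
                 n_orthologs = counts, agios = agios, pairs = pairs),
            class = "agios_matrix")
}

#' Render an AGIOS matrix in the triangular table convention
#'
#' @param x an `agios_matrix`.
#' @return character matrix: diagonal = gene counts, lower = ortholog
#'   counts, upper = AGIOS percentages truncated to 2 decimals.
#' @export
format_agios_matrix <- function(x) {
  stopifnot(inherits(x, "agios_matrix"))
  k <- length(x$genome_ids)
  out <- matrix("", k, k, dimnames = list(x$genome_ids, x$genome_ids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[i, j] <- if (i == j) as.character(x$gene_counts[i])
      else if (i > j) as.character(x$n_orthologs[i, j])
      else if (is.na(x$agios[i, j])) "NA"
      else fmt_percent(x$agios[i, j])
  }
  out
}

#' @export
print.agios_matrix <- function(x, ...) {
  cat("AGIOS matrix (", length(x$genome_ids), " genomes)\n",
      "diagonal: gene counts; below: shared orthologs; above: AGIOS %\n\n",
      sep = "")
  print(format_agios_matrix(x), quote = FALSE)
  invisible(x)
}

#' Long-format view of an AGIOS matrix
#'
#' @param x an `agios_matrix`.
#' @return data frame `genome_a`, `genome_b`, `n_orthologs`, `agios`.
#' @export
agios_long <- function(x) {
  stopifnot(inherits(x, "agios_matrix"))
  ids <- x$genome_ids
  rows <- list()
  for (i in seq_len(length(ids) - 1)) for (j in seq(i + 1, length(ids))) {
    rows[[length(rows) + 1L]] <- data.frame(
      genome_a = ids[i], genome_b = ids[j],
      n_orthologs = x$n_orthologs[i, j], agios = x$agios[i, j],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write an AGIOS matrix (triangular TSV plus long-format TSV)
#'
#' @param x an `agios_matrix`.
#' @param path output TSV for the triangular table.
#' @param long_path optional output TSV for the long format.
#' @return `path`, invisibly.
#' @export
write_agios_matrix <- function(x, path, long_path = NULL) {
  m <- format_agios_matrix(x)
  df <- data.frame(genome = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path))
    utils::write.table(agios_long(x), long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
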