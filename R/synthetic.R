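# Synthetic genome-pair generator with known ortholog ground truth.
#
# The generator defines the conditions every other module is validated
# against: an ancestor of random ORFs, and a derivative produced by
# per-site substitution (uniform replacement by one of the three other
# bases, so expected per-site identity is exactly 1 - p), optional
# frame-preserving indels, gene loss and gene gain.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.random_codons <- function(ncod, gc) {
  # non-stop codons at the target composition
  if (ncod == 0L) return(character(0))
  s <- seq_len(ncod) * 3L
  cod <- substring(paste(.sample_bases(3L * ncod, gc), collapse = ""),
                   s - 2L, s)
  repeat {
    bad <- cod %in% .STOP_CODONS
    if (!any(bad)) break
    nb <- sum(bad)
    sb <- seq_len(nb) * 3L
    cod[bad] <- substring(paste(.sample_bases(3L * nb, gc), collapse = ""),
                          sb - 2L, sb)
  }
  cod
}

.random_orf <- function(len, gc) {
  paste0("ATG", paste(.random_codons(len / 3L - 2L, gc), collapse = ""),
         sample(.STOP_CODONS, 1L))
}

.assemble_genome <- function(genome_id, orfs, strands, gc, spacer_mean) {
  n <- length(orfs)
  spacers <- vapply(pmax(20L, rpois(n + 1L, spacer_mean)),
                    function(l) paste(.sample_bases(l, gc), collapse = ""),
                    character(1))
  pieces <- character(2L * n + 1L)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- spacers[i]
    pos <- pos + nchar(spacers[i])
    starts[i] <- pos + 1L
    pieces[2L * i] <- if (strands[i] == "-") revcomp(orfs[i]) else orfs[i]
    pos <- pos + nchar(orfs[i])
  }
  pieces[2L * n + 1L] <- spacers[n + 1L]
  contig <- paste(pieces, collapse = "")
  ann <- data.frame(seqid = "contig_1", start = starts,
                    end = starts + nchar(orfs) - 1L, strand = strands,
                    gene_id = names(orfs), stringsAsFactors = FALSE)
  genome <- genome_record(genome_id, c(contig_1 = contig))
  list(genome = genome, annotations = ann)
}

#' Generate a random ancestor genome with annotated ORFs
#'
#' Genes begin with ATG, end with a stop codon and contain no internal
#' stop; gene lengths are normal around `mean_gene_length` (rounded to
#' multiples of 3, minimum 33 bp); intergenic spacers are random sequence
#' at the same base composition; genes fall on either strand. For total
#' lengths of 50 kb and more the realized G+C fraction concentrates within
#' about two points of `gc_target`.
#'
#' @param n_genes number of genes (>= 1).
#' @param mean_gene_length mean gene length in bp, a multiple of 3, at
#'   least 33.
#' @param gc_target target G+C fraction in (0, 1).
#' @param seed RNG seed (determinism across runs).
#' @param spacer_mean mean intergenic spacer length in bp.
#' @param neg_strand_prob probability a gene lies on the reverse strand.
#' @return list with `genome` (a [genome_record()]), `annotations`
#'   (1-based GFF-style data frame) and `genes` (the extracted
#'   `gene_table`); attribute `gc_target` is carried for the evolver.
#' @export
generate_ancestor <- function(n_genes, mean_gene_length = 900,
                              gc_target = 0.5, seed = NULL,
                              spacer_mean = 100, neg_strand_prob = 0.3) {
  stopifnot(n_genes >= 1)
  if (mean_gene_length %% 3 != 0)
    stop("mean_gene_length must be a multiple of 3")
  if (mean_gene_length < 33)
    stop("mean_gene_length below 33 bp leaves no room for start, stop ",
         "and a coding body")
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  lens <- pmax(33L, 3L * as.integer(round(
    rnorm(n_genes, mean_gene_length, mean_gene_length / 6) / 3)))
  orfs <- vapply(lens, .random_orf, character(1), gc = gc_target)
  names(orfs) <- sprintf("anc_%04d", seq_len(n_genes))
  strands <- sample(c("+", "-"), n_genes, replace = TRUE,
                    prob = c(1 - neg_strand_prob, neg_strand_prob))
  asm <- .assemble_genome("ancestor", orfs, strands, gc_target, spacer_mean)
  genes <- extract_genes(asm$genome, asm$annotations)
  structure(list(genome = asm$genome, annotations = asm$annotations,
                 genes = genes),
            gc_target = gc_target, spacer_mean = spacer_mean)
}

#' Evolution parameters for [evolve_genome()]
#'
#' @param substitution_p per-site substitution probability in \[0, 1); a
#'   hit site is replaced by one of the three other bases uniformly, so
#'   the expected per-site identity is exactly `1 - substitution_p`.
#' @param indel_rate expected number of indel events per gene (>= 0).
#' @param indel_length_mean mean indel length in bp (> 0).
#' @param gene_loss_p per-gene loss probability.
#' @param gene_gain_n number of novel random ORFs appended.
#' @param seed RNG seed.
#' @param frame_preserving indel lengths forced to multiples of 3
#'   (default); set `FALSE` to generate frameshifts and exercise the
#'   gene-flagging path.
#' @param strict flag genes whose start/stop was destroyed instead of
#'   repairing them (default repairs, keeping gene counts stable).
#' @return an `evolution_params` object.
#' @export
evolution_params <- function(substitution_p = 0, indel_rate = 0,
                             indel_length_mean = 6, gene_loss_p = 0,
                             gene_gain_n = 0, seed = NULL,
                             frame_preserving = TRUE, strict = FALSE) {
  stopifnot(substitution_p >= 0, substitution_p < 1, indel_rate >= 0,
            indel_length_mean > 0, gene_loss_p >= 0, gene_loss_p <= 1,
            gene_gain_n >= 0)
  structure(list(substitution_p = substitution_p, indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 gene_loss_p = gene_loss_p,
                 gene_gain_n = as.integer(gene_gain_n), seed = seed,
                 frame_preserving = frame_preserving, strict = strict),
            class = "evolution_params")
}

.mutate_sites <- function(nt, p) {
  if (p <= 0) return(nt)
  v <- strsplit(nt, "")[[1]]
  hit <- which(runif(length(v)) < p)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (h in hit) v[h] <- sample(bases[bases != v[h]], 1L)
  }
  paste(v, collapse = "")
}

.repair_orf <- function(nt, ancestral) {
  # restore destroyed start/stop and revert codons mutated into stops
  s <- seq_len(nchar(nt) %/% 3L) * 3L
  cod <- substring(nt, s - 2L, s)
  anc_cod <- substring(ancestral, s - 2L, s)
  ncod <- length(cod)
  cod[1L] <- "ATG"
  if (!cod[ncod] %in% .STOP_CODONS) cod[ncod] <- anc_cod[ncod]
  internal <- which(cod[-c(1L, ncod)] %in% .STOP_CODONS) + 1L
  cod[internal] <- anc_cod[internal]
  paste(cod, collapse = "")
}

.apply_indels <- function(nt, params, gc) {
  n_events <- rpois(1L, params$indel_rate)
  for (e in seq_len(n_events)) {
    len <- if (params$frame_preserving)
      3L * max(1L, rpois(1L, params$indel_length_mean / 3))
    else max(1L, rpois(1L, params$indel_length_mean))
    ncod <- nchar(nt) %/% 3L
    if (ncod < 4L) next
    # codon-boundary position strictly inside the gene body
    at <- 3L * sample(seq_len(ncod - 2L), 1L)
    if (runif(1) < 0.5) {  # insertion
      ins <- if (params$frame_preserving)
        paste(.random_codons(len %/% 3L, gc), collapse = "")
      else paste(.sample_bases(len, gc), collapse = "")
      nt <- paste0(substr(nt, 1L, at), ins,
                   substr(nt, at + 1L, nchar(nt)))
    } else {  # deletion
      if (at + len > nchar(nt) - 3L) next
      nt <- paste0(substr(nt, 1L, at),
                   substr(nt, at + len + 1L, nchar(nt)))
    }
  }
  nt
}

#' Evolve a genome from an ancestor with known ground truth
#'
#' Applies per-site substitution, optional indels, gene loss and gene gain
#' to the ancestor's genes, rebuilds a derived genome (fresh spacers,
#' ancestral strands), and returns the truth table linking ancestor to
#' derived genes. Substituted start/stop codons and codons mutated into
#' internal stops are repaired by reverting to the ancestral codon (or, in
#' strict mode, the gene is left as mutated and will be flagged during
#' extraction).
#'
#' @param ancestor result of [generate_ancestor()].
#' @param params an [evolution_params()].
#' @param genome_id id of the derived genome.
#' @return list with `genome`, `annotations`, `genes` (extracted
#'   `gene_table`) and `truth` (data frame `ancestor_gene_id`,
#'   `derived_gene_id`, `status` in retained/lost/gained; every ancestor
#'   gene appears exactly once, gained genes carry `NA` ancestors).
#' @examples
#' \donttest{
#' anc <- generate_ancestor(20, 300, 0.5, seed = 1)
#' der <- evolve_genome(anc, evolution_params(substitution_p = 0.02,
#'                                            seed = 2))
#' table(der$truth$status)
#' }
#' @export
evolve_genome <- function(ancestor, params = evolution_params(),
                          genome_id = "derived") {
  stopifnot(inherits(params, "evolution_params"),
            is.list(ancestor), !is.null(ancestor$genes))
  gc <- attr(ancestor, "gc_target") %||% 0.5
  spacer_mean <- attr(ancestor, "spacer_mean") %||% 100
  if (!is.null(params$seed)) set.seed(params$seed)
  anc <- ancestor$genes
  n <- nrow(anc)
  lost <- runif(n) < params$gene_loss_p
  kept <- which(!lost)
  orfs <- character(length(kept))
  for (ii in seq_along(kept)) {
    i <- kept[ii]
    nt <- .mutate_sites(anc$nt_seq[i], params$substitution_p)
    if (!params$strict) nt <- .repair_orf(nt, anc$nt_seq[i])
    if (params$indel_rate > 0) nt <- .apply_indels(nt, params, gc)
    orfs[ii] <- nt
  }
  der_ids <- sprintf("der_%04d", kept)
  names(orfs) <- der_ids
  strands <- anc$strand[kept]
  if (params$gene_gain_n > 0L) {
    gain_len <- pmax(33L, 3L * as.integer(round(
      rnorm(params$gene_gain_n, 900, 150) / 3)))
    gains <- vapply(gain_len, .random_orf, character(1), gc = gc)
    names(gains) <- sprintf("gain_%03d", seq_len(params$gene_gain_n))
    orfs <- c(orfs, gains)
    strands <- c(strands, sample(c("+", "-"), params$gene_gain_n,
                                 replace = TRUE))
  }
  asm <- .assemble_genome(genome_id, orfs, strands, gc, spacer_mean)
  genes <- extract_genes(asm$genome, asm$annotations)
  truth <- data.frame(
    ancestor_gene_id = c(anc$gene_id,
                         rep(NA_character_, params$gene_gain_n)),
    derived_gene_id = c(ifelse(lost, NA_character_,
                               sprintf("der_%04d", seq_len(n))),
                        if (params$gene_gain_n > 0L)
                          sprintf("gain_%03d",
                                  seq_len(params$gene_gain_n))),
    status = c(ifelse(lost, "lost", "retained"),
               rep("gained", params$gene_gain_n)),
    stringsAsFactors = FALSE
  )
  list(genome = asm$genome, annotations = asm$annotations, genes = genes,
       truth = truth)
}

#' Closed-form expected alignment identity under substitution only
#'
#' With indels disabled, each site is changed with probability
#' `substitution_p` and always to a different base, so the expected
#' per-site identity is exactly `100 * (1 - substitution_p)`. Used by
#' parameter-recovery tests.
#'
#' @param params an [evolution_params()].
#' @return expected identity percentage.
#' @export
expected_identity <- function(params) {
  stopifnot(inherits(params, "evolution_params"))
  if (params$indel_rate > 0)
    stop("no closed-form expectation with indels enabled")
  100 * (1 - params$substitution_p)
}

#' Write a simulated genome (FASTA + annotation TSV + truth TSV)
#'
#' @param sim result of [generate_ancestor()] or [evolve_genome()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default: the genome id).
#' @return named character vector of the files written, invisibly.
#' @export
write_simulated_genome <- function(sim, dir, prefix = NULL) {
  stopifnot(is.list(sim), !is.null(sim$genome))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- prefix %||% sim$genome$genome_id
  fa <- file.path(dir, paste0(prefix, ".fna"))
  ann <- file.path(dir, paste0(prefix, ".tsv"))
  write_fasta(sim$genome$contigs, fa)
  write_annotations(sim$annotations, ann)
  out <- c(fasta = fa, annotations = ann)
  if (!is.null(sim$truth)) {
    tt <- file.path(dir, paste0(prefix, "_truth.tsv"))
    utils::write.table(sim$truth, tt, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- c(out, truth = tt)
  }
  invisible(out)
}
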