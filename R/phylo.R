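# Distance-based phylogeny: distances from a multiple alignment,
# Saitou-Nei neighbor joining, column bootstrap with majority-rule
# consensus, and newick round-tripping. Tree algorithms are delegated to
# ape behind this module's interface; branch-length clamping, gap
# handling, replicate collapsing and support bookkeeping live here.

.msa_matrix <- function(msa) {
  if (is.matrix(msa)) {
    if (is.null(rownames(msa))) stop("MSA matrix must have row names")
    return(msa)
  }
  stopifnot(is.character(msa))
  if (is.null(names(msa)) || anyDuplicated(names(msa)))
    stop("MSA must be a named character vector with unique taxon ids")
  if (length(unique(nchar(msa))) != 1L)
    stop("MSA rows have unequal lengths")
  if (length(msa) < 3L) stop("at least 3 taxa required")
  do.call(rbind, strsplit(toupper(msa), ""))
}

.MODEL_MAP <- c(p_distance = "raw", jukes_cantor = "JC69",
                kimura_2p = "K80")

.dist_from_charmat <- function(mat, model) {
  dna <- ape::as.DNAbin(apply(mat, 2, tolower))
  rownames(dna) <- rownames(mat)
  d <- suppressWarnings(
    ape::dist.dna(dna, model = .MODEL_MAP[[model]],
                  pairwise.deletion = TRUE, as.matrix = TRUE))
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stop("distance undefined for pair '", rownames(d)[bad[1]], "' / '",
         colnames(d)[bad[2]], "': no comparable columns or divergence ",
         "beyond the model's range")
  }
  d
}

#' Pairwise distances from a multiple sequence alignment
#'
#' Distances are computed over columns without a gap (or `N`) in either
#' member of the pair (pairwise deletion). Models: `p_distance`
#' (proportion of differing sites), `jukes_cantor`
#' (`-3/4 * log(1 - 4p/3)`), `kimura_2p` (separate transition and
#' transversion rates).
#'
#' @param msa named character vector of equal-length aligned sequences
#'   (or a character matrix with row names), at least 3 taxa. Read aligned
#'   FASTA with [read_fasta()]`(..., alphabet = "any")`.
#' @param model distance model.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_from_msa <- function(msa, model = c("p_distance", "jukes_cantor",
                                             "kimura_2p")) {
  model <- match.arg(model)
  .dist_from_charmat(.msa_matrix(msa), model)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (standard Q criterion). Negative
#' branch-length estimates, which NJ can produce on non-additive input,
#' are clamped to zero.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   at least 3 taxa.
#' @return an unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining requires at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8) || any(d < 0) ||
      any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Bootstrap majority-rule consensus tree
#'
#' Resamples alignment columns with replacement `n_replicates` times,
#' builds a neighbor-joining tree per replicate (zero-length internal
#' edges collapsed, so signal-free data yields unresolved consensus
#' rather than arbitrary resolutions of ties), and returns the strict
#' majority-rule (>50%) consensus with bipartition frequencies (percent,
#' integers) as node labels.
#'
#' @inheritParams distance_from_msa
#' @param n_replicates number of bootstrap replicates (the convention in
#'   genome-description papers is 1,000).
#' @param seed RNG seed for reproducible resampling.
#' @return a `phylo` consensus tree; node labels carry supports, attribute
#'   `n_replicates` the replicate count.
#' @export
bootstrap_consensus <- function(msa, model = "p_distance",
                                n_replicates = 100, seed = NULL) {
  stopifnot(n_replicates >= 1)
  mat <- .msa_matrix(msa)
  if (!is.null(seed)) set.seed(seed)
  trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    tr <- neighbor_joining(.dist_from_charmat(mat[, cols, drop = FALSE],
                                              model))
    trees[[r]] <- ape::di2multi(tr, tol = 1e-10)
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)  # keeps clades with freq > 0.5
  freq <- ape::prop.clades(cons, trees, rooted = FALSE)
  freq[is.na(freq)] <- n_replicates  # the trivial (root) partition
  cons$node.label <- as.character(round(100 * freq / n_replicates))
  attr(cons, "n_replicates") <- n_replicates
  attr(cons, "model") <- model
  cons
}

#' Root a tree on a named outgroup leaf (display only)
#'
#' Trees are estimated unrooted; rooting on an outgroup is presentation.
#'
#' @param tree a `phylo`.
#' @param outgroup leaf label.
#' @return rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Write / read newick
#'
#' Round-trips topology, labels, branch lengths (6 decimals) and support
#' labels. `read_newick` reports the position of the first unbalanced
#' parenthesis on malformed input.
#'
#' @param tree a `phylo`.
#' @param path file path.
#' @return `write_newick`: `path` invisibly; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at end of input")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}
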