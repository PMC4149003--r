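# COG functional-category profiles from precomputed gene-to-category
# assignments. The BLASTP search against the COG database itself is a
# database-bound step outside this package: assignments are input.

.COG_ORDER <- c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N", "Z",
                "W", "U", "O", "C", "G", "E", "F", "H", "I", "P", "Q", "R",
                "S")
.COG_DESC <- c(
  J = "Translation", A = "RNA processing and modification",
  K = "Transcription", L = "Replication, recombination and repair",
  B = "Chromatin structure and dynamics",
  D = "Cell cycle control, mitosis and meiosis", Y = "Nuclear structure",
  V = "Defense mechanisms", T = "Signal transduction mechanisms",
  M = "Cell wall/membrane biogenesis", N = "Cell motility",
  Z = "Cytoskeleton", W = "Extracellular structures",
  U = "Intracellular trafficking and secretion",
  O = "Posttranslational modification, protein turnover, chaperones",
  C = "Energy production and conversion",
  G = "Carbohydrate transport and metabolism",
  E = "Amino acid transport and metabolism",
  F = "Nucleotide transport and metabolism",
  H = "Coenzyme transport and metabolism",
  I = "Lipid transport and metabolism",
  P = "Inorganic ion transport and metabolism",
  Q = "Secondary metabolites biosynthesis, transport and catabolism",
  R = "General function prediction only", S = "Function unknown")

#' The 25 general COG functional categories
#'
#' @return data frame `code`, `description` in the conventional table
#'   order (J through S).
#' @export
cog_categories <- function() {
  data.frame(code = .COG_ORDER, description = unname(.COG_DESC[.COG_ORDER]),
             stringsAsFactors = FALSE)
}

#' COG category profile of a genome
#'
#' Counts genes per category (a gene carrying several category letters
#' increments each of them) and computes percentages against
#' `n_protein_coding` — the protein-coding gene count, the denominator
#' genome-description papers use for their COG table. (Their general
#' statistics table may use the total gene count as denominator instead;
#' pass it via `n_protein_coding` to get that convention.) Percentages are
#' truncated to 2 decimals.
#'
#' @param assignments data frame with columns `gene_id` and `categories`
#'   (a string of category letters, optionally comma-separated; empty =
#'   not in COGs), or the path of such a TSV.
#' @param n_protein_coding percentage denominator; at least the number of
#'   assigned genes.
#' @param genome_id label carried in the result.
#' @return a `cog_profile`: `counts` (named vector over the 25 letters),
#'   `percents`, `not_in_cogs` count/percent, `denominator`.
#' @examples
#' a <- data.frame(gene_id = c("g1", "g2"), categories = c("G", "GK"))
#' cog_profile(a, n_protein_coding = 4)$counts[["G"]] # 2
#' @export
cog_profile <- function(assignments, n_protein_coding, genome_id = "genome") {
  if (.is_string(assignments)) assignments <- read_cog_assignments(assignments)
  stopifnot(is.data.frame(assignments),
            all(c("gene_id", "categories") %in% names(assignments)))
  if (anyDuplicated(assignments$gene_id))
    stop("duplicate gene_id(s) in COG assignments")
  cats <- gsub("[ ,]", "", as.character(assignments$categories))
  cats[is.na(cats)] <- ""
  letters_per_gene <- strsplit(cats, "")
  all_letters <- unlist(letters_per_gene, use.names = FALSE)
  bad <- setdiff(unique(all_letters), .COG_ORDER)
  if (length(bad))
    stop("unknown COG category letter(s): ", paste(bad, collapse = ", "))
  n_assigned <- sum(lengths(letters_per_gene) > 0L)
  if (n_protein_coding < n_assigned)
    stop("denominator (", n_protein_coding,
         ") smaller than the number of assigned genes (", n_assigned, ")")
  counts <- vapply(.COG_ORDER, function(l) sum(all_letters == l), numeric(1))
  not_in <- n_protein_coding - n_assigned
  structure(
    list(genome_id = genome_id, counts = counts,
         percents = trunc_percent(100 * counts / n_protein_coding, 2),
         not_in_cogs = not_in,
         not_in_cogs_percent = trunc_percent(100 * not_in / n_protein_coding,
                                             2),
         n_assigned = n_assigned, denominator = n_protein_coding),
    class = "cog_profile"
  )
}

#' @export
print.cog_profile <- function(x, ...) {
  cat("COG profile:", x$genome_id, "(denominator", x$denominator, "genes)\n")
  df <- as.data.frame(x)
  df$percent <- fmt_percent(df$percent)
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @method as.data.frame cog_profile
#' @export
as.data.frame.cog_profile <- function(x, ...) {
  data.frame(
    code = c(.COG_ORDER, "-"),
    count = c(unname(x$counts), x$not_in_cogs),
    percent = c(unname(x$percents), x$not_in_cogs_percent),
    description = c(unname(.COG_DESC[.COG_ORDER]), "Not in COGs"),
    stringsAsFactors = FALSE
  )
}

#' Read a gene-to-COG assignment TSV (`gene_id`, `categories`)
#' @param path TSV file.
#' @return data frame of assignments.
#' @export
read_cog_assignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "categories") %in% names(df)))
    stop("COG assignment table needs columns gene_id, categories")
  df
}

#' Write a COG profile as a category table TSV
#' @param x a `cog_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cog_table <- function(x, path) {
  stopifnot(inherits(x, "cog_profile"))
  df <- as.data.frame(x)
  df$percent <- fmt_percent(df$percent)
  names(df) <- c("Code", "Value", "% of total", "Description")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare COG profiles across genomes
#'
#' @param profiles list of `cog_profile` objects (at least 2).
#' @return list with `wide_counts` and `wide_percents` (category x genome
#'   matrices, categories in the fixed order J..S plus `-`) and `long`
#'   (data frame `genome_id`, `code`, `count`, `percent`).
#' @export
compare_cog_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 2,
            all(vapply(profiles, inherits, logical(1), "cog_profile")))
  ids <- vapply(profiles, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) stop("duplicate genome ids among profiles")
  codes <- c(.COG_ORDER, "-")
  wc <- sapply(profiles, function(p) c(p$counts, `-` = p$not_in_cogs))
  wp <- sapply(profiles, function(p)
    c(p$percents, `-` = p$not_in_cogs_percent))
  dimnames(wc) <- dimnames(wp) <- list(codes, ids)
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(genome_id = p$genome_id, code = codes,
               count = c(unname(p$counts), p$not_in_cogs),
               percent = c(unname(p$percents), p$not_in_cogs_percent),
               stringsAsFactors = FALSE)))
  list(wide_counts = wc, wide_percents = wp, long = long)
}
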