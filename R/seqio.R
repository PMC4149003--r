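# Sequence/annotation I/O, gene extraction and translation, and the
# genome-level statistics that go into a genome-description table.
#
# Coordinate conventions: 0-based half-open inside the package; 1-based
# inclusive (GFF style) at every I/O boundary, converted on read.

.DNA_CHARS <- c("A", "C", "G", "T", "N")
.AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Read a FASTA file
#'
#' Records are uppercased and sequences concatenated across wrapped lines.
#' Record ids are the header up to the first whitespace. Duplicate ids,
#' empty files/sequences and characters outside the allowed alphabet (for
#' DNA: A, C, G, T, N — other ambiguity codes are rejected) are errors
#' naming the offending record.
#'
#' @param path FASTA file.
#' @param alphabet `"DNA"`, `"protein"`, or `"any"` (no character check).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "protein", "any")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e),
                                           ")", call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  if (alphabet != "any") {
    allowed <- if (alphabet == "DNA") .DNA_CHARS else .AA_CHARS
    for (i in seq_along(seqs)) {
      bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), allowed)
      if (length(bad))
        stop("record '", ids[i], "' contains illegal ", alphabet,
             " characters: ", paste(bad, collapse = ", "))
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' A genome: a named set of contig sequences
#'
#' @param genome_id label for the genome.
#' @param contigs named character vector of DNA sequences (A, C, G, T, N;
#'   case-insensitive). Contig ids must be unique and sequences non-empty.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs) {
  stopifnot(.is_string(genome_id), is.character(contigs), length(contigs) > 0)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)) ||
      any(!nzchar(names(contigs))))
    stop("contigs must carry unique non-empty names")
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L))
    stop("empty contig sequence(s): ",
         paste(names(contigs)[nchar(contigs) == 0L], collapse = ", "))
  for (i in seq_along(contigs)) {
    bad <- setdiff(unique(strsplit(contigs[[i]], "")[[1]]), .DNA_CHARS)
    if (length(bad))
      stop("contig '", names(contigs)[i], "' contains illegal characters: ",
           paste(bad, collapse = ", "))
  }
  structure(list(genome_id = genome_id, contigs = contigs),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("Genome '", x$genome_id, "': ", length(x$contigs), " contig(s), ",
      sum(nchar(x$contigs)), " bp\n", sep = "")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' @param path FASTA of contigs.
#' @param genome_id genome label (default: file name without extension).
#' @return a [genome_record()].
#' @export
read_genome <- function(path, genome_id = NULL) {
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  genome_record(genome_id, read_fasta(path, alphabet = "DNA"))
}

#' Translate a coding sequence (bacterial code, table 11)
#'
#' Codons are mapped with the bacterial/archaeal genetic code; the standard
#' and table-11 codon-to-amino-acid maps coincide, differing only in
#' permitted start codons, which are not enforced here. A terminal stop is
#' stripped. Codons containing `N` translate to `X`.
#'
#' @param nt DNA string, length at least 3.
#' @param code genetic code identifier passed to
#'   [Biostrings::getGeneticCode()].
#' @return the protein string, with attributes `frame_ok` (length divisible
#'   by 3; trailing partial codons are dropped when it is not) and
#'   `internal_stop` (a `*` occurs before the final codon).
#' @export
translate_cds <- function(nt, code = "11") {
  stopifnot(.is_string(nt))
  nt <- toupper(nt)
  if (nchar(nt) < 3L) stop("coding sequence shorter than one codon")
  frame_ok <- nchar(nt) %% 3L == 0L
  ncod <- nchar(nt) %/% 3L
  starts <- seq(1L, by = 3L, length.out = ncod)
  codons <- substring(nt, starts, starts + 2L)
  tab <- Biostrings::getGeneticCode(code)
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  terminal_stop <- aa[ncod] == "*"
  if (terminal_stop) aa <- aa[-ncod]
  internal_stop <- any(aa == "*")
  structure(paste(aa, collapse = ""),
            frame_ok = frame_ok, internal_stop = internal_stop,
            terminal_stop = terminal_stop)
}

#' Extract annotated genes from a genome
#'
#' Takes a GFF-flavored coordinate table (1-based inclusive `start`/`end`
#' on the forward strand) and returns each gene's coding-strand nucleotide
#' sequence (reverse-complemented for `-` strand genes) and its
#' translation. Genes whose length is not a multiple of 3 or that contain
#' an internal stop codon are retained but flagged (`valid = FALSE`) and
#' excluded from protein-level orthology by downstream defaults — draft
#' annotations commonly contain pseudogene fragments.
#'
#' @param genome a [genome_record()].
#' @param annotations data frame with columns `contig` (or `seqid`),
#'   `start`, `end`, `strand` (`+`/`-`), `gene_id`.
#' @param code genetic code for translation.
#' @return a `gene_table` data frame: `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end` (0-based half-open), `strand`, `nt_seq`, `aa_seq`,
#'   `frame_ok`, `internal_stop`, `valid`.
#' @export
extract_genes <- function(genome, annotations, code = "11") {
  stopifnot(inherits(genome, "genome_record"), is.data.frame(annotations))
  ann <- annotations
  if (!"contig" %in% names(ann) && "seqid" %in% names(ann))
    ann$contig <- ann$seqid
  need <- c("contig", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(ann)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id(s): ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  n <- nrow(ann)
  nt <- character(n); aa <- character(n)
  frame_ok <- logical(n); internal_stop <- logical(n)
  for (i in seq_len(n)) {
    gid <- ann$gene_id[i]
    if (!ann$contig[i] %in% names(genome$contigs))
      stop("gene '", gid, "': unknown contig '", ann$contig[i], "'")
    ctg <- genome$contigs[[ann$contig[i]]]
    s1 <- ann$start[i]; e1 <- ann$end[i]
    if (is.na(s1) || is.na(e1) || s1 < 1 || e1 < s1 || e1 > nchar(ctg))
      stop("gene '", gid, "': coordinates [", s1, ",", e1,
           "] out of bounds for contig '", ann$contig[i], "' (length ",
           nchar(ctg), ")")
    if (!ann$strand[i] %in% c("+", "-"))
      stop("gene '", gid, "': strand must be '+' or '-'")
    seq <- substr(ctg, s1, e1)
    if (ann$strand[i] == "-") seq <- revcomp(seq)
    nt[i] <- seq
    tr <- translate_cds(seq, code)
    aa[i] <- as.character(tr)
    frame_ok[i] <- attr(tr, "frame_ok")
    internal_stop[i] <- attr(tr, "internal_stop")
  }
  out <- data.frame(
    gene_id = ann$gene_id, genome_id = genome$genome_id,
    contig_id = ann$contig,
    start = ann$start - 1L, end = ann$end,  # 0-based half-open
    strand = ann$strand, nt_seq = nt, aa_seq = aa,
    frame_ok = frame_ok, internal_stop = internal_stop,
    valid = frame_ok & !internal_stop,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Read a GFF-flavored annotation TSV
#'
#' Expects a tab-separated table with a header containing at least `seqid`
#' (or `contig`), `start`, `end`, `strand`, `gene_id`; `start`/`end` are
#' 1-based inclusive.
#'
#' @param path TSV file.
#' @return data frame of annotations.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  ann
}

#' Write an annotation table as TSV (1-based inclusive coordinates)
#' @param annotations annotation data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' G+C content of a genome
#'
#' The denominator is the total assembly length including `N` positions
#' (matching the convention "genome size = total length"); only `G` and
#' `C` count in the numerator. The percentage is rounded to 1 decimal, the
#' one table quantity conventionally rounded rather than truncated.
#'
#' @param genome a [genome_record()].
#' @return list with `gc_bp`, `genome_size_bp`, `gc_percent`.
#' @examples
#' g <- genome_record("g", c(c1 = "ATGC"))
#' gc_content(g)$gc_percent # 50
#' @export
gc_content <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  chars <- strsplit(paste(genome$contigs, collapse = ""), "")[[1]]
  gc_bp <- sum(chars %in% c("G", "C"))
  size <- length(chars)
  list(gc_bp = gc_bp, genome_size_bp = size,
       gc_percent = round(100 * gc_bp / size, 1))
}

#' Coding density of a genome
#'
#' `coding_bp` is the length of the union of coding intervals per contig —
#' overlapping and nested genes are counted once. The percentage is
#' truncated to 2 decimals.
#'
#' @param genome a [genome_record()].
#' @param genes a `gene_table` from [extract_genes()] (0-based half-open
#'   `start`/`end`).
#' @return list with `coding_bp`, `coding_percent`.
#' @export
coding_density <- function(genome, genes) {
  stopifnot(inherits(genome, "genome_record"), is.data.frame(genes))
  size <- sum(nchar(genome$contigs))
  if (nrow(genes) == 0L)
    return(list(coding_bp = 0L, coding_percent = 0))
  if (!all(genes$contig_id %in% names(genome$contigs)))
    stop("genes reference contigs absent from the genome")
  coding_bp <- 0L
  for (ctg in unique(genes$contig_id)) {
    g <- genes[genes$contig_id == ctg, ]
    ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
    coding_bp <- coding_bp + sum(IRanges::width(ir))
  }
  list(coding_bp = coding_bp,
       coding_percent = trunc_percent(100 * coding_bp / size, 2))
}

#' Genome statistics report
#'
#' Aggregates assembly size, G+C content, coding density and gene count in
#' the layout of a genome-description table. G+C is rounded to 1 decimal;
#' other percentages truncated to 2.
#'
#' @param genome a [genome_record()].
#' @param genes a `gene_table` (may be empty).
#' @return an object of class `genome_stats`.
#' @export
genome_report <- function(genome, genes) {
  gc <- gc_content(genome)
  cd <- coding_density(genome, genes)
  structure(
    list(genome_id = genome$genome_id,
         genome_size_bp = gc$genome_size_bp,
         gc_bp = gc$gc_bp, gc_percent = gc$gc_percent,
         coding_bp = cd$coding_bp, coding_percent = cd$coding_percent,
         n_genes = nrow(genes),
         n_valid_genes = if (nrow(genes)) sum(genes$valid) else 0L),
    class = "genome_stats"
  )
}

#' @export
print.genome_stats <- function(x, ...) {
  cat("Genome statistics:", x$genome_id, "\n")
  cat(sprintf("  %-28s %12s %8s\n", "Attribute", "Value", "% of total"))
  cat(sprintf("  %-28s %12s\n", "Genome size (bp)",
              format(x$genome_size_bp, big.mark = ",")))
  cat(sprintf("  %-28s %12s %8.1f\n", "DNA G+C content (bp)",
              format(x$gc_bp, big.mark = ","), x$gc_percent))
  cat(sprintf("  %-28s %12s %8s\n", "DNA coding region (bp)",
              format(x$coding_bp, big.mark = ","),
              fmt_percent(x$coding_percent)))
  cat(sprintf("  %-28s %12d\n", "Genes", x$n_genes))
  cat(sprintf("  %-28s %12d\n", "Genes passing CDS checks", x$n_valid_genes))
  invisible(x)
}

#' Write a genome statistics report as TSV
#' @param stats a `genome_stats` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_report <- function(stats, path) {
  stopifnot(inherits(stats, "genome_stats"))
  df <- data.frame(
    attribute = c("Genome size (bp)", "DNA G+C content (bp)",
                  "DNA coding region (bp)", "Genes",
                  "Genes passing CDS checks"),
    value = c(stats$genome_size_bp, stats$gc_bp, stats$coding_bp,
              stats$n_genes, stats$n_valid_genes),
    percent_of_total = c("", sprintf("%.1f", stats$gc_percent),
                         fmt_percent(stats$coding_percent), "", ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
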