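# Small in-code fixtures shared across test files.

tiny_genome <- function() {
  # contig_1: one + strand gene at [4,12], one - strand gene at [16,24]
  # (1-based inclusive); contig_2 unannotated.
  genome_record("tiny", c(
    contig_1 = "TTTATGAAATAGCCCCTACTTCATGGGG",
    contig_2 = "ACGTACGTNN"
  ))
}

tiny_annotations <- function() {
  data.frame(
    seqid = c("contig_1", "contig_1"),
    start = c(4L, 16L), end = c(12L, 24L),
    strand = c("+", "-"),
    gene_id = c("g_plus", "g_minus"),
    stringsAsFactors = FALSE
  )
}

# A 4-taxon alignment whose every column supports the same 2+2 split.
split_msa <- function(ncol = 20) {
  stopifnot(ncol %% 2 == 0)
  col_ab <- paste(rep(c("A", "G"), ncol / 2), collapse = "")
  col_cd <- paste(rep(c("C", "T"), ncol / 2), collapse = "")
  c(a = col_ab, b = col_ab, c = col_cd, d = col_cd)
}
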