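#' Published reference statistics for the Collinsella comparison set
#'
#' Bundled copies of the published genome-description statistics for
#' *Collinsella massiliensis* GD3 and the comparator genomes used in its
#' circumscription: the nucleotide/gene count table, the COG category
#' counts, the comparison-genome metadata (deposited accessions, sizes,
#' G+C, gene counts) and the published ortholog-count/AGIOS matrix
#' (diagonal: protein-coding gene counts; lower triangle: shared ortholog
#' counts; upper triangle: AGIOS percentages). These are inputs for the
#' table-convention calculations and context for integration runs against
#' the deposited assemblies; recomputing the matrix itself requires
#' downloading those assemblies.
#'
#' @return list of data frames: `genome_counts`, `cog_counts`,
#'   `comparison_genomes`, `ortholog_agios`.
#' @export
collinsella_reference <- function() {
  dir <- system.file("extdata", "collinsella", package = "agios")
  rd <- function(f, ...) utils::read.delim(file.path(dir, f),
                                           stringsAsFactors = FALSE, ...)
  list(
    genome_counts = rd("genome_counts.tsv"),
    cog_counts = rd("cog_counts.tsv"),
    comparison_genomes = rd("comparison_genomes.tsv"),
    ortholog_agios = rd("ortholog_agios_matrix.tsv", check.names = FALSE)
  )
}
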