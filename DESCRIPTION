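Package: agios
Title: Genome Sequence Similarity for Bacterial Species Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genome-sequence side of bacterial taxonomy
    ("taxono-genomics"): pairwise global and local alignment with affine
    gap costs, reciprocal-best-hit ortholog detection between annotated
    genomes, the AGIOS statistic (average genomic identity of orthologous
    gene sequences), 16S rRNA identity against the 98.7 percent
    species-delineation threshold, neighbor-joining phylogenies with
    bootstrap majority-rule consensus, genome nucleotide/coding statistics
    and COG functional category profiles. Includes a genome-pair simulator
    with known ortholog ground truth for validating the whole pipeline
    without downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
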