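test_that("ancestor generation is deterministic and produces valid ORFs", {
  a1 <- generate_ancestor(n_genes = 40, mean_gene_length = 300,
                          gc_target = 0.65, seed = 7)
  a2 <- generate_ancestor(n_genes = 40, mean_gene_length = 300,
                          gc_target = 0.65, seed = 7)
  expect_identical(a1$genome$contigs, a2$genome$contigs)
  expect_identical(a1$genes$nt_seq, a2$genes$nt_seq)

  expect_equal(nrow(a1$genes), 40L)
  expect_true(all(substr(a1$genes$nt_seq, 1, 3) == "ATG"))
  last3 <- substring(a1$genes$nt_seq, nchar(a1$genes$nt_seq) - 2)
  expect_true(all(last3 %in% c("TAA", "TAG", "TGA")))
  expect_true(all(a1$genes$valid))
  expect_true(all(nchar(a1$genes$nt_seq) %% 3 == 0))
})

test_that("realized G+C concentrates near the target on long genomes", {
  a <- generate_ancestor(n_genes = 60, mean_gene_length = 900,
                         gc_target = 0.5, seed = 19)
  gc <- gc_content(a$genome)
  expect_gte(gc$genome_size_bp, 50000)
  expect_lt(abs(gc$gc_percent - 50), 2)
  b <- generate_ancestor(n_genes = 60, mean_gene_length = 900,
                         gc_target = 0.65, seed = 20)
  expect_lt(abs(gc_content(b$genome)$gc_percent - 65), 2)
})

test_that("infeasible generator parameters are rejected", {
  expect_error(generate_ancestor(10, mean_gene_length = 3), "33")
  expect_error(generate_ancestor(10, mean_gene_length = 100), "multiple of 3")
  expect_error(generate_ancestor(10, gc_target = 1.2), "gc_target")
})

test_that("all-zero parameters give an identity evolution", {
  anc <- generate_ancestor(n_genes = 15, mean_gene_length = 300,
                           gc_target = 0.5, seed = 23)
  der <- evolve_genome(anc, evolution_params(seed = 24))
  expect_identical(der$genes$nt_seq, anc$genes$nt_seq)
  expect_true(all(der$truth$status == "retained"))
  expect_equal(der$truth$derived_gene_id, sub("anc", "der",
                                              der$truth$ancestor_gene_id))
})

test_that("evolution is byte-deterministic under a fixed seed", {
  anc <- generate_ancestor(n_genes = 15, mean_gene_length = 300,
                           gc_target = 0.5, seed = 25)
  p <- evolution_params(substitution_p = 0.05, indel_rate = 0.5,
                        gene_loss_p = 0.1, gene_gain_n = 2, seed = 26)
  d1 <- evolve_genome(anc, p)
  d2 <- evolve_genome(anc, p)
  expect_identical(d1$genome$contigs, d2$genome$contigs)
  expect_identical(d1$truth, d2$truth)
})

test_that("per-gene identity converges to 100(1-p) under substitutions only", {
  anc <- generate_ancestor(n_genes = 100, mean_gene_length = 900,
                           gc_target = 0.5, seed = 27)
  der <- evolve_genome(anc, evolution_params(substitution_p = 0.10,
                                             seed = 28))
  # Hamming identity on equal-length retained genes, no alignment involved
  ids <- mapply(function(x, y) {
    cx <- strsplit(x, "")[[1]]
    cy <- strsplit(y, "")[[1]]
    100 * mean(cx == cy)
  }, anc$genes$nt_seq, der$genes$nt_seq)
  expect_lt(abs(mean(ids) - 90), 1)
})

test_that("gene loss and gain are recorded in the truth table", {
  anc <- generate_ancestor(n_genes = 100, mean_gene_length = 150,
                           gc_target = 0.5, seed = 29)
  der <- evolve_genome(anc, evolution_params(gene_loss_p = 0.1,
                                             gene_gain_n = 5, seed = 30))
  tt <- der$truth
  n_lost <- sum(tt$status == "lost")
  expect_gt(n_lost, 2)            # ~Binomial(100, 0.1) under this seed
  expect_lt(n_lost, 25)
  expect_equal(sum(tt$status == "gained"), 5)
  expect_true(all(is.na(tt$ancestor_gene_id[tt$status == "gained"])))
  expect_true(all(is.na(tt$derived_gene_id[tt$status == "lost"])))
  # every ancestor gene appears exactly once
  expect_setequal(tt$ancestor_gene_id[!is.na(tt$ancestor_gene_id)],
                  anc$genes$gene_id)
  expect_equal(nrow(der$genes), 100 - n_lost + 5)
})

test_that("frameshift mode produces genes the extractor flags", {
  anc <- generate_ancestor(n_genes = 20, mean_gene_length = 300,
                           gc_target = 0.5, seed = 33)
  der <- evolve_genome(anc, evolution_params(indel_rate = 2,
                                             indel_length_mean = 4,
                                             frame_preserving = FALSE,
                                             seed = 34))
  expect_gt(sum(!der$genes$valid), 0)
})

test_that("frame-preserving indels keep genes translatable", {
  anc <- generate_ancestor(n_genes = 20, mean_gene_length = 300,
                           gc_target = 0.5, seed = 35)
  der <- evolve_genome(anc, evolution_params(substitution_p = 0.02,
                                             indel_rate = 1,
                                             indel_length_mean = 9,
                                             seed = 36))
  expect_true(all(der$genes$frame_ok))
  expect_true(all(der$genes$valid))
})

test_that("expected_identity is the closed form, substitutions only", {
  expect_equal(expected_identity(evolution_params(substitution_p = 0)), 100)
  expect_equal(expected_identity(evolution_params(substitution_p = 0.05)), 95)
  expect_equal(expected_identity(evolution_params(substitution_p = 0.10)), 90)
  expect_error(expected_identity(evolution_params(indel_rate = 1)),
               "indels")
  expect_error(evolution_params(substitution_p = 1.5))
})

test_that("simulated genomes round-trip through FASTA/TSV on disk", {
  anc <- generate_ancestor(n_genes = 5, mean_gene_length = 150,
                           gc_target = 0.5, seed = 37)
  dir <- withr::local_tempdir()
  files <- write_simulated_genome(anc, dir, prefix = "anc")
  g <- read_genome(files[["fasta"]], genome_id = "anc")
  ann <- read_annotations(files[["annotations"]])
  genes <- extract_genes(g, ann)
  expect_identical(genes$nt_seq, anc$genes$nt_seq)
})
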