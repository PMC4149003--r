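test_that("global alignment of trivial cases behaves", {
  aln <- needleman_wunsch("ACGT", "ACGT")
  expect_equal(aln$identity_percent, 100)
  expect_equal(aln$n_gap_columns, 0L)
  expect_equal(aln$score, 20)

  aln2 <- needleman_wunsch("AAAA", "TTTT")
  expect_equal(aln2$n_match, 0L)
  expect_equal(aln2$identity_percent, 0)

  expect_error(needleman_wunsch("", "ACGT"), "non-empty")
  expect_error(needleman_wunsch("ACGT", "MKLV"), "alphabet")
})

test_that("global score and alignment match plain-R enumeration", {
  # spec'd worked case: ACGT vs ACG
  expect_equal(needleman_wunsch("ACGT", "ACG")$score,
               r_enum_global("ACGT", "ACG"))
  set.seed(42)
  for (i in 1:25) {
    a <- random_seq(sample(1:5, 1))
    b <- random_seq(sample(1:5, 1))
    aln <- needleman_wunsch(a, b)
    expect_equal(aln$score, r_enum_global(a, b), info = paste(a, b))
    # removing gaps recovers the inputs
    expect_equal(gsub("-", "", aln$aligned_a, fixed = TRUE), a)
    expect_equal(gsub("-", "", aln$aligned_b, fixed = TRUE), b)
  }
})

test_that("global and local scores agree with Biostrings pairwiseAlignment", {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                baseOnly = TRUE)
  set.seed(7)
  for (i in 1:20) {
    a <- random_seq(sample(5:60, 1))
    b <- random_seq(sample(5:60, 1))
    ref_g <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = m,
                                           gapOpening = 10,
                                           gapExtension = 0.5,
                                           type = "global")
    expect_equal(needleman_wunsch(a, b)$score, Biostrings::score(ref_g))
    ref_l <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = m,
                                           gapOpening = 10,
                                           gapExtension = 0.5,
                                           type = "local")
    expect_equal(smith_waterman(a, b)$score,
                 max(0, Biostrings::score(ref_l)))
  }
})

test_that("alignment score is symmetric and monotone under shared suffix", {
  set.seed(11)
  for (i in 1:10) {
    a <- random_seq(sample(3:20, 1))
    b <- random_seq(sample(3:20, 1))
    expect_equal(needleman_wunsch(a, b)$score, needleman_wunsch(b, a)$score)
    suf <- random_seq(5)
    expect_gte(needleman_wunsch(paste0(a, suf), paste0(b, suf))$score,
               needleman_wunsch(a, b)$score)
  }
})

test_that("self-alignment identity is exactly 100 for any sequence", {
  set.seed(3)
  for (len in c(1, 7, 50)) {
    s <- random_seq(len, c("A", "C", "G", "T", "N"))
    expect_identical(needleman_wunsch(s, s)$identity_percent, 100)
  }
})

test_that("N scores as mismatch against everything including N", {
  sch <- scoring_scheme()
  expect_equal(sch$matrix["N", "N"], sch$mismatch)
  expect_equal(needleman_wunsch("NNNN", "NNNN")$score, 4 * sch$mismatch)
})

test_that("local alignment allows the empty alignment and reports bounds", {
  aln <- smith_waterman("ACGT", "ACGT")
  expect_equal(aln$score, needleman_wunsch("ACGT", "ACGT")$score)
  expect_equal(aln$identity_percent, 100)

  none <- smith_waterman("A", "C")
  expect_equal(none$score, 0)
  expect_equal(none$n_columns, 0L)

  mid <- smith_waterman("TTTACGTTT", "GGGACGGGG")
  expect_equal(mid$aligned_a, "ACG")
  expect_equal(c(mid$start_a, mid$end_a), c(4, 6))
})

test_that("local score equals the exhaustive substring-pair oracle", {
  sub <- scoring_scheme()$matrix
  set.seed(5)
  for (i in 1:15) {
    a <- random_seq(sample(2:7, 1))
    b <- random_seq(sample(2:7, 1))
    expect_equal(smith_waterman(a, b)$score,
                 agios:::brute_local_score_cpp(a, b, sub, "ACGTN", 10, 0.5),
                 info = paste(a, b))
  }
})

test_that("semiglobal alignment leaves terminal gaps free", {
  aln <- needleman_wunsch("AAAGGG", "GGGCCC", type = "semiglobal")
  expect_equal(aln$score, 15)  # the GGG overlap, no terminal penalty
  expect_gte(aln$score, needleman_wunsch("AAAGGG", "GGGCCC")$score)
})

test_that("percent_identity modes use their denominators", {
  # 10 columns, 2 gap columns, 8 matches
  aln <- structure(list(aligned_a = "ACGTACGT--", aligned_b = "ACGTACGTTT",
                        score = 0, n_match = 8L, n_columns = 10L,
                        n_gap_columns = 2L, identity_percent = 80),
                   class = "pairwise_alignment")
  expect_equal(percent_identity(aln, "all_columns"), 80)
  expect_equal(percent_identity(aln, "ungapped_columns"), 100)
  expect_equal(percent_identity(aln, "shorter_seq"), 100)
  # hand-counted 5-column alignment: ACG-T vs ACGAT -> 4 matches
  a5 <- needleman_wunsch("ACGT", "ACGAT")
  expect_equal(a5$n_match, 4L)
  expect_equal(percent_identity(a5, "all_columns"), 80)

  identical_aln <- needleman_wunsch("ACGT", "ACGT")
  for (m in c("all_columns", "ungapped_columns", "shorter_seq"))
    expect_equal(percent_identity(identical_aln, m), 100)
})

test_that("scoring scheme validates its invariants", {
  expect_error(scoring_scheme(match = -4, mismatch = 5), "match")
  expect_error(scoring_scheme(gap_open = 1, gap_extend = 2), "gap_extend")
  expect_s3_class(scoring_scheme("protein"), "scoring_scheme")
  expect_true("W" %in% rownames(scoring_scheme("protein")$matrix))
})
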