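random_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- runif(nrow(tr$edge), 0.5, 3)
  tr
}

test_that("distances from an MSA follow the chosen model", {
  msa <- c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC")
  expect_true(all(distance_from_msa(msa) == 0))

  msa2 <- c(a = "AAAAAAAAAA", b = "CCAAAAAAAA", c = "AAAAAAAAAA")
  d <- distance_from_msa(msa2, "p_distance")
  expect_equal(d["a", "b"], 0.2)
  dj <- distance_from_msa(msa2, "jukes_cantor")
  expect_equal(dj["a", "b"], -3 / 4 * log(1 - 4 / 3 * 0.2))

  # pairwise deletion: the gapped column is excluded only for pairs
  # involving the gapped row
  msa3 <- c(a = "AC-TACGTAC", b = "ACGTACGTAC", c = "ATTTACGTAC")
  d3 <- distance_from_msa(msa3)
  expect_equal(d3["a", "b"], 0)
  expect_equal(d3["a", "c"], 1 / 9)
  expect_equal(d3["b", "c"], 2 / 10)

  expect_error(distance_from_msa(c(a = "ACG", b = "AC", c = "ACG")),
               "unequal")
  expect_error(distance_from_msa(c(a = "AC", b = "AC")), "3 taxa")
  expect_error(distance_from_msa(c(a = "A-", b = "-C", c = "AC")),
               "a.*b|no comparable")
})

test_that("three taxa solve the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  # three-point formulas: x = (dab+dac-dbc)/2 etc.
  lens <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(lens[["a"]], 1)
  expect_equal(lens[["b"]], 2)
  expect_equal(lens[["c"]], 3)
  expect_error(neighbor_joining(D[1:2, 1:2]), "3 taxa")
})

test_that("NJ inverts additive matrices exactly (topology and lengths)", {
  for (seed in 1:12) {
    n <- sample(4:8, 1)
    tr <- random_additive_tree(n, seed)
    D <- ape::cophenetic.phylo(tr)
    out <- neighbor_joining(D)
    expect_equal(max(abs(ape::cophenetic.phylo(out)[rownames(D), colnames(D)]
                         - D)), 0, tolerance = 1e-10)
    expect_equal(ape::dist.topo(ape::unroot(tr), out), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap consensus is deterministic under a seed", {
  msa <- split_msa(20)
  c1 <- bootstrap_consensus(msa, n_replicates = 50, seed = 9)
  c2 <- bootstrap_consensus(msa, n_replicates = 50, seed = 9)
  expect_equal(ape::write.tree(c1), ape::write.tree(c2))
})

test_that("an unambiguous 2+2 split gets support 100", {
  cons <- bootstrap_consensus(split_msa(20), n_replicates = 100, seed = 4)
  expect_true(all(as.numeric(cons$node.label) == 100))
  # exactly one non-trivial bipartition: {a,b} | {c,d}
  parts <- ape::prop.part(cons)
  expect_equal(cons$Nnode, 2L)
})

test_that("identical sequences give a star-like consensus", {
  msa <- setNames(rep(strrep("ACGT", 5), 5),
                  c("t1", "t2", "t3", "t4", "t5"))
  cons <- bootstrap_consensus(msa, n_replicates = 30, seed = 3)
  expect_equal(cons$Nnode, 1L)  # no resolved bipartition
})

test_that("no column variation reproduces the point-estimate tree", {
  # every column identical: any resample gives the same distances
  base_col <- c(a = "A", b = "A", c = "C", d = "C")
  msa <- vapply(names(base_col), function(t)
    strrep(base_col[[t]], 12), character(1))
  point <- neighbor_joining(distance_from_msa(msa))
  boot <- bootstrap_consensus(msa, n_replicates = 1, seed = 1)
  expect_equal(ape::dist.topo(ape::di2multi(point, tol = 1e-10), boot), 0,
               ignore_attr = TRUE)
})

test_that("consensus supports are invariant to taxon order", {
  msa <- split_msa(20)
  c1 <- bootstrap_consensus(msa, n_replicates = 60, seed = 5)
  c2 <- bootstrap_consensus(msa[c("d", "b", "a", "c")],
                            n_replicates = 60, seed = 5)
  key <- function(tr) {
    s <- as.numeric(tr$node.label[-1])
    sort(s)
  }
  expect_equal(key(c1), key(c2))
})

test_that("newick round-trips and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".nwk")
  tr <- random_additive_tree(6, 77)
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-5)  # newick stores 6 significant digits

  writeLines("(A:1,B:2,(C:3,D:4):5);", f)
  tr2 <- read_newick(f)
  expect_equal(ape::Ntip(tr2), 4L)
  internal <- tr2$edge[, 2] > ape::Ntip(tr2)
  expect_equal(tr2$edge.length[internal], 5)

  writeLines("(A:1,(B:2;", f)
  expect_error(read_newick(f), "malformed|unbalanced")
  writeLines("(A:1,B:2));", f)
  expect_error(read_newick(f), "position")
})

test_that("outgroup rooting is a display option over the unrooted tree", {
  tr <- random_additive_tree(5, 55)
  rooted <- root_on_outgroup(ape::unroot(tr), tr$tip.label[1])
  expect_true(ape::is.rooted(rooted))
  expect_error(root_on_outgroup(tr, "not_a_leaf"), "not a leaf")
})
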