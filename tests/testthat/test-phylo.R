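test_that("p-distances count mismatches over comparable columns", {
  aln <- as_alignment(c(a = "ACDE", b = "ACDE"))
  expect_equal(p_distance_matrix(aln)["a", "b"], 0)
  aln <- as_alignment(c(a = "ACDE", b = "ACDF"))
  expect_equal(p_distance_matrix(aln)["a", "b"], 0.25)
})

test_that("pairwise and complete deletion differ as hand-counted on a gapped toy", {
  aln <- as_alignment(c(a = "AC-EF", b = "ACDEF", c = "GCDEF"))
  Dp <- p_distance_matrix(aln, "pairwise")
  # a vs b: comparable cols 1,2,4,5 all equal -> 0
  expect_equal(Dp["a", "b"], 0)
  # a vs c: comparable cols 1,2,4,5; col1 differs -> 1/4
  expect_equal(Dp["a", "c"], 0.25)
  Dc <- p_distance_matrix(aln, "complete")
  # column 3 dropped for everyone: a vs c over cols 1,2,4,5 -> 1/4,
  # b vs c -> 1/4 (pairwise would give 1/5)
  expect_equal(Dc["b", "c"], 0.25)
  expect_equal(Dp["b", "c"], 0.2)
  expect_error(p_distance_matrix(as_alignment(c(a = "A-", b = "-A"))),
               "comparable")
})

test_that("20-state Jukes-Cantor correction matches its closed form", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.5), 0.70985, tolerance = 1e-4)
  expect_equal(jc_correct(0.5, "nt4"), -0.75 * log(1 - 2 / 3))
  expect_error(jc_correct(0.95), "saturated")
  # strictly increasing on [0, 19/20)
  p <- seq(0, 0.94, by = 0.01)
  expect_true(all(diff(jc_correct(p)) > 0))
  expect_true(all(jc_correct(p) >= p - 1e-12))  # correction only inflates
})

test_that("three-taxon NJ reproduces the three-point formulas", {
  D <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["a"]], 0.1)
  expect_equal(bl[["b"]], 0.2)
  expect_equal(bl[["c"]], 0.3)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ inverts additive distance matrices exactly", {
  # the worked 4-taxon case ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  expect_identical(tree_bipartitions(tr), "C|D")  # AB|CD split
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4],
                                                    LETTERS[1:4]],
               D, tolerance = 1e-10)

  # property: random trees up to 12 taxa, distances from the tree
  set.seed(11)
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    ref <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.1, 1))
    D <- as.matrix(ape::cophenetic.phylo(ref))
    tr <- nj_tree(D)
    expect_setequal(tree_bipartitions(tr), tree_bipartitions(ref))
    expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D),
                                                      rownames(D)],
                 D, tolerance = 1e-8)
  }
})

test_that("degenerate equidistant input yields a stable deterministic tree", {
  D <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D) <- 0
  t1 <- newick_write(nj_tree(D))
  t2 <- newick_write(nj_tree(D))
  expect_identical(t1, t2)
  expect_true(all(nj_tree(D)$edge.length >= 0))
})

test_that("negative NJ branch lengths are clamped with the deficit moved to the sister", {
  # A is close to everyone, B far: joining the (A,B) cherry gives A a
  # negative length (-2.5), which moves onto B so the AB path is kept
  D <- matrix(c(0, 2, 1, 1,
                2, 0, 8, 8,
                1, 8, 0, 1,
                1, 8, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 0)
  expect_equal(bl[["A"]] + bl[["B"]], D["A", "B"])
  # the trifurcation endgame simply clamps residual negatives to zero
  D3 <- matrix(c(0, 1, 6, 1, 0, 2, 6, 2, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_true(all(nj_tree(D3)$edge.length >= 0))
})

test_that("bootstrap supports hit 100 on perfectly clade-diagnostic alignments", {
  backbone <- strrep("K", 40)
  rows <- c(a1 = paste0(backbone, strrep("A", 20)),
            a2 = paste0(backbone, strrep("A", 20)),
            b1 = paste0(backbone, strrep("C", 20)),
            b2 = paste0(backbone, strrep("C", 20)),
            c1 = paste0(backbone, strrep("F", 20)),
            c2 = paste0(backbone, strrep("F", 20)))
  aln <- as_alignment(rows)
  tr <- bootstrap_support(aln, B = 50, seed = 1)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_true(length(sup) >= 2)
  expect_true(all(sup == 100))
})

test_that("single-replicate supports are 0 or 100", {
  fam <- simulate_family_sequences(n_per_clade = 2, seq_length = 60,
                                   divergence = 0.05,
                                   inter_clade_divergence = 0.4,
                                   signature_spec = list(
                                     GbpA = c("5" = "R"), DppA = c("5" = "D"),
                                     HbpA2 = c("5" = "T")),
                                   seed = 5)
  aln <- as_alignment(setNames(unclass(fam)[seq_along(fam)], names(fam)))
  tr <- bootstrap_support(aln, B = 1, seed = 2)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(sup %in% c(0, 100)))
  expect_identical(attr(tr, "bootstrap_B"), 1L)
})

test_that("Newick serialization round-trips and rejects malformed input", {
  tr <- newick_read("(A:1,B:2,(C:3,D:4)95:1);")
  expect_equal(length(tr$tip.label), 4L)
  expect_identical(tree_bipartitions(tr), "C|D")
  expect_true(95 %in% tr$node.label)
  back <- newick_read(newick_write(tr))
  expect_setequal(tree_bipartitions(back), tree_bipartitions(tr))
  expect_equal(sum(back$edge.length), sum(tr$edge.length))
  expect_error(newick_read("(A:1,B:2,(C:3,D:4);"), "[Nn]ewick")
})
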