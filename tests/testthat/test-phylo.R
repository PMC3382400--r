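test_that("p-distance and Poisson behave per closed form", {
  aln <- aa_alignment(c("a", "b", "c"),
                      c("MKWL", "MKAI", "MKWL"))
  D <- distance_matrix(aln)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], 0.5)   # 2 of 4 comparable sites differ
  expect_true(isSymmetric(unname(D)))

  P <- distance_matrix(aln, model = "poisson")
  expect_equal(P["a", "c"], 0)
  expect_equal(P["a", "b"], -log(1 - 0.5))
  expect_gt(P["a", "b"], D["a", "b"])  # correction inflates distances
})

test_that("gaps and X are excluded pairwise; complete deletion drops columns", {
  aln <- aa_alignment(c("a", "b", "c"),
                      c("MKW-A", "MKWLA", "MXWLA"))
  Dp <- distance_matrix(aln)
  expect_equal(Dp["a", "b"], 0)     # 4 comparable, 0 differ
  expect_equal(Dp["b", "c"], 0)     # X site dropped pairwise
  Dc <- distance_matrix(aln, deletion = "complete")
  expect_equal(unname(Dc["a", "b"]), 0)  # only gap/X-free columns used
})

test_that("degenerate pairs are rejected with names", {
  aln <- aa_alignment(c("a", "b", "c"),
                      c("MK--", "--WL", "MKWL"))
  expect_error(distance_matrix(aln), "no comparable sites.*'a'.*'b'")
  aln2 <- aa_alignment(c("a", "b", "c"), c("MKWL", "AVER", "MKWL"))
  expect_error(distance_matrix(aln2, model = "poisson"), "p = 1")
})

test_that("three taxa follow the closed-form three-point lengths", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  lens <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                   tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(lens[["a"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["b"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["c"]], (4 + 5 - 3) / 2)
})

test_that("an additive 4-taxon matrix is recovered exactly", {
  # tree: (a:1,b:2):1 joined to (c:3,d:4)
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[letters[1:4],
                                                 letters[1:4]] - D)), 0,
               tolerance = 1e-12)
})

test_that("equal distances give a deterministic lowest-index join", {
  D <- matrix(1, 5, 5) - diag(5)
  dimnames(D) <- list(paste0("t", 1:5), paste0("t", 1:5))
  n1 <- to_newick(neighbor_joining(D))
  n2 <- to_newick(neighbor_joining(D))
  expect_identical(n1, n2)
  # first join is (t1, t2) by the tie rule
  expect_match(n1, "\\(t1:[0-9.]+,t2:", fixed = FALSE)
})

test_that("asymmetry and non-finite distances are rejected", {
  D <- matrix(c(0, 1, 2, 3,
                1, 0, 1, 2,
                2, 1.5, 0, 1,
                3, 2, 1, 0), 4, 4, byrow = TRUE)
  expect_error(neighbor_joining(D), "symmetric")
  D2 <- matrix(0, 3, 3); D2[1, 2] <- D2[2, 1] <- Inf
  expect_error(neighbor_joining(D2), "non-finite")
})

test_that("NJ agrees with the independent ape implementation", {
  skip_if_not_installed("phangorn")
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    tr0 <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr0)
    ours <- neighbor_joining(D)
    theirs <- ape::nj(D)
    expect_equal(phangorn::RF.dist(ours, theirs), 0)
  }
})

test_that("taxon relabeling/permutation leaves the unrooted topology fixed", {
  skip_if_not_installed("phangorn")
  set.seed(53)
  tr0 <- ape::rtree(7)
  D <- ape::cophenetic.phylo(tr0)
  perm <- sample(nrow(D))
  ours <- neighbor_joining(D)
  permuted <- neighbor_joining(D[perm, perm])
  expect_equal(phangorn::RF.dist(ours, permuted), 0)
})

test_that("Newick output is 6-decimal, parseable, and label-safe", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a sp", "b", "c"), c("a sp", "b", "c")))
  tr <- neighbor_joining(D)
  s <- to_newick(tr)
  expect_match(s, "^\\(.*\\);$")
  expect_match(s, "a_sp:1\\.000000")
  back <- ape::read.tree(text = s)
  expect_equal(sort(back$tip.label), sort(c("a_sp", "b", "c")))
  expect_equal(sum(back$edge.length), sum(tr$edge.length),
               tolerance = 1e-6)
  f <- withr::local_tempfile(fileext = ".nwk")
  to_newick(tr, path = f)
  expect_identical(readLines(f), s)
})

test_that("distance matrices round-trip through TSV and PHYLIP square", {
  aln <- aa_alignment(c("a", "b", "c"), c("MKWL", "MKAI", "MKWI"))
  D <- distance_matrix(aln)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(D, f)
  back <- read_distance_tsv(f)
  expect_equal(back, D, ignore_attr = TRUE)
  # PHYLIP-style square input
  f2 <- withr::local_tempfile(fileext = ".dist")
  writeLines(c("3",
               paste("a", paste(D["a", ], collapse = " ")),
               paste("b", paste(D["b", ], collapse = " ")),
               paste("c", paste(D["c", ], collapse = " "))), f2)
  back2 <- read_distance_tsv(f2)
  expect_equal(unname(back2), unname(D), ignore_attr = TRUE)
})
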