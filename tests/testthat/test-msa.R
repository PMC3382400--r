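test_that("scoring scheme validates gap penalties", {
  expect_error(scoring_scheme(gap_open = -1, gap_extend = -2),
               "gap_open <= gap_extend")
  expect_error(scoring_scheme(gap_open = -10, gap_extend = 0), "< 0")
  s <- scoring_scheme("PAM250", gap_open = -8, gap_extend = -1)
  expect_equal(s$name, "PAM250")
})

test_that("pairwise alignment of identical sequences is gapless", {
  s <- scoring_scheme()
  chars <- c("M", "K", "W", "V", "E")
  res <- pairwise_align(c(a = "MKWVE"), c(b = "MKWVE"), s)
  expect_identical(res$alignment$rows, c("MKWVE", "MKWVE"))
  expect_equal(res$score, sum(diag(s$matrix[chars, chars])))
})

test_that("aligning a residue against a run forces one match plus a gap", {
  s <- scoring_scheme()
  res <- pairwise_align(c(a = "A"), c(b = "AAAAAA"), s)
  expect_equal(res$score,
               s$matrix["A", "A"] + s$gap_open + 4 * s$gap_extend)
  expect_equal(sum(strsplit(res$alignment$rows[1], "")[[1]] != "-"), 1L)
})

test_that("DP score equals exhaustive alignment enumeration", {
  set.seed(7)
  schemes <- list(scoring_scheme(),
                  scoring_scheme(gap_open = -4, gap_extend = -2))
  alpha <- c("A", "C", "G", "T")
  for (s in schemes) {
    for (rep in 1:40) {
      a <- random_aa_string(sample(1:6, 1), alpha)
      b <- random_aa_string(sample(1:6, 1), alpha)
      got <- pairwise_align(c(a = a), c(b = b), s)$score
      expect_equal(got, oracle_align_score(a, b, s),
                   info = paste(a, b, s$gap_open))
    }
  }
})

test_that("guide tree joins lowest-index pair on ties", {
  rec <- protein_records(id = c("x", "y", "z"),
                         sequence = rep("MKWVE", 3))
  gt <- guide_tree(rec)
  expect_equal(gt$merge[1, ], c(-1L, -2L))
  expect_equal(gt$height[1], 0)
  rec2 <- protein_records(id = c("x", "y"), sequence = c("MKWVE", "MKWVE"))
  gt2 <- guide_tree(rec2)
  expect_equal(nrow(gt2$merge), 1L)
})

test_that("guide tree heights are non-decreasing", {
  cfg <- sim_config(seed = 5, n_species = 4, core_length = 60,
                    variable_nterm_max = 5, n_anchor_sites = 4)
  sim <- simulate_families(cfg)
  gt <- guide_tree(sim$records)
  expect_true(all(diff(gt$height) >= -1e-12))
  expect_setequal(gt$labels, sim$records$id)
})

test_that("progressive alignment reduces to pairwise for two records", {
  rec <- protein_records(id = c("a", "b"),
                         sequence = c("MKWLE", "MKWALE"))
  aln <- progressive_align(rec)
  pw <- pairwise_align(rec[1, ], rec[2, ])$alignment
  expect_identical(aln$rows, pw$rows)
})

test_that("progressive alignment of identical sequences is one gapless block", {
  rec <- protein_records(id = paste0("s", 1:4),
                         sequence = rep("MKWVEDA", 4))
  aln <- progressive_align(rec)
  expect_identical(aln$rows, rep("MKWVEDA", 4))
})

test_that("every MSA row ungaps to its input, in input order", {
  cfg <- sim_config(seed = 21, n_species = 5, core_length = 70,
                    variable_nterm_max = 10, n_anchor_sites = 5)
  sim <- simulate_families(cfg)
  aln <- progressive_align(sim$records)
  expect_identical(aln$ids, sim$records$id)
  expect_identical(ungap(aln$rows), sim$records$sequence)
})

test_that("planted anchor sites are recovered column-to-column", {
  cfg <- sim_config(seed = 9, n_species = 5, core_length = 80,
                    variable_nterm_max = 12, anchor_rate_multiplier = 0,
                    n_anchor_sites = 6,
                    families = list(list(name = "famA", class_label = "I",
                                         diagnostic = c("W", "W"))))
  sim <- simulate_families(cfg)
  aln <- progressive_align(sim$records)
  # each simulated anchor site must land in a single alignment column
  for (core_pos in cfg$anchor_positions) {
    at <- sim$anchor_truth[sim$anchor_truth$core_position == core_pos, ]
    cols <- vapply(seq_len(nrow(at)), function(k) {
      row <- aln$rows[match(at$id[k], aln$ids)]
      res2col <- which(strsplit(row, "")[[1]] != "-")
      res2col[at$position[k]]
    }, 0L)
    expect_length(unique(cols), 1L)
  }
})

test_that("sum-of-pairs score does not decrease when duplicating a row", {
  cfg <- sim_config(seed = 3, n_species = 3, core_length = 60,
                    variable_nterm_max = 5, n_anchor_sites = 4,
                    families = default_families()[1:2])
  sim <- simulate_families(cfg)
  rec <- sim$records
  s <- scoring_scheme()
  base_score <- alignment_sp_score(progressive_align(rec, s), s)
  dup <- rec[c(seq_len(nrow(rec)), 1L), ]
  dup$id[nrow(dup)] <- "dup_of_first"
  class(dup) <- c("protein_records", "data.frame")
  dup_score <- alignment_sp_score(progressive_align(dup, s), s)
  expect_gte(dup_score, base_score)
})
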