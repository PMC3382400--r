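test_that("default catalog carries the prose-named reference residues", {
  cat_df <- load_anchor_catalog()
  has <- function(ref, pos, exp, role)
    any(cat_df$reference_id == ref & cat_df$position == pos &
          cat_df$expected == exp & cat_df$role == role)
  expect_true(has("mouse_eIF4E", 56, "W", "cap"))
  expect_true(has("mouse_eIF4E", 102, "W", "cap"))
  expect_true(has("mouse_eIF4E", 166, "W", "cap"))
  expect_true(has("dmel_eIF4E-1", 251, "S", "phospho"))
  expect_true(has("human_eIF4E", 43, "W", "class_diagnostic"))
  expect_true(has("human_eIF4E", 56, "W", "class_diagnostic"))
  expect_true(has("dmel_eIF4E-3", 103, "W", "scaffold_binding"))
  expect_true(has("dmel_4E-HP", 46, "N", "scaffold_binding"))
})

test_that("catalog validation names the offending line", {
  cat_df <- load_anchor_catalog()
  f <- withr::local_tempfile(fileext = ".tsv")
  bad <- cat_df
  bad$position[2] <- 0L
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_anchor_catalog(f), "line 3.*positive")
  bad <- cat_df
  bad$role[1] <- "mystery"
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_anchor_catalog(f), "line 2.*unknown role")
})

test_that("anchors map through gapless and gapped alignments", {
  aln <- aa_alignment(c("ref", "tgt"), c("MKWL", "MKWL"))
  anc <- list(reference_id = "ref", position = 3L)
  mp <- map_anchor(aln, anc, "tgt")
  expect_equal(mp$observed, "W")
  expect_equal(mp$target_position, 3L)

  # hand-traced: reference MK-W vs target MKAW, anchor position 3 (W)
  aln2 <- aa_alignment(c("ref", "tgt"), c("MK-W", "MKAW"))
  mp2 <- map_anchor(aln2, anc, "tgt")
  expect_equal(mp2$column, 4L)
  expect_equal(mp2$observed, "W")
  expect_equal(mp2$target_position, 4L)

  # target gapped at the mapped column
  aln3 <- aa_alignment(c("ref", "tgt"), c("MKW", "MK-"))
  mp3 <- map_anchor(aln3, anc, "tgt")
  expect_equal(mp3$observed, "-")
  expect_true(is.na(mp3$target_position))

  expect_error(map_anchor(aln, list(reference_id = "ref", position = 9L),
                          "tgt"), "beyond")
  expect_error(map_anchor(aln, list(reference_id = "nope", position = 1L),
                          "tgt"), "reference row")
})

test_that("substitution statuses follow the group logic", {
  g <- conservative_groups()
  expect_equal(substitution_status("W", "W", g), "conserved")
  expect_equal(substitution_status("W", "F", g), "conservative_substitution")
  expect_equal(substitution_status("L", "H", g), "nonconservative")
  expect_equal(substitution_status("S", "P", g), "nonconservative")
  expect_equal(substitution_status("S", "-", g), "deleted")
  expect_equal(substitution_status("S", "X", g), "undetermined")
})

test_that("substitution report covers rows x anchors with a total partition", {
  aln <- aa_alignment(c("dref", "s1", "s2", "s3"),
                      c("MWLS", "MFHS", "MW-X", "MWLP"))
  cat_df <- as_anchor_catalog(data.frame(
    reference_id = "dref", position = c(2L, 3L, 4L),
    expected = c("W", "L", "S"),
    role = c("cap", "scaffold_binding", "phospho"),
    scheme = "family_local", stringsAsFactors = FALSE))
  rep_df <- report_substitutions(aln, cat_df)
  expect_equal(nrow(rep_df), 4L * 3L)
  expect_true(all(rep_df$status %in%
    c("conserved", "conservative_substitution", "nonconservative",
      "deleted", "undetermined")))
  get <- function(id, pos) rep_df$status[rep_df$sequence_id == id &
                                           rep_df$position == pos]
  expect_equal(get("s1", 2), "conservative_substitution")  # W>F
  expect_equal(get("s1", 3), "nonconservative")            # L>H
  expect_equal(get("s2", 3), "deleted")
  expect_equal(get("s2", 4), "undetermined")
  expect_equal(get("s3", 4), "nonconservative")            # S>P
  # the reference maps onto itself as conserved at its own coordinate
  expect_true(all(rep_df$status[rep_df$sequence_id == "dref"] ==
                    "conserved"))
  expect_equal(rep_df$target_position[rep_df$sequence_id == "dref"],
               c(2L, 3L, 4L))
})

test_that("gap-only columns never change the report", {
  aln <- aa_alignment(c("dref", "s1"), c("MWLS", "MFHS"))
  cat_df <- as_anchor_catalog(data.frame(
    reference_id = "dref", position = c(2L, 4L), expected = c("W", "S"),
    role = c("cap", "phospho"), scheme = "family_local",
    stringsAsFactors = FALSE))
  base <- report_substitutions(aln, cat_df)
  padded <- aa_alignment(aln$ids, c("M-WL-S", "M-FH-S"))
  got <- report_substitutions(padded, cat_df)
  expect_equal(got$status, base$status)
  expect_equal(got$observed, base$observed)
  expect_equal(got$target_position, base$target_position)
})

test_that("missing reference rows are reported by name", {
  aln <- aa_alignment(c("s1", "s2"), c("MWLS", "MFHS"))
  cat_df <- as_anchor_catalog(data.frame(
    reference_id = "absent_ref", position = 1L, expected = "M",
    role = "cap", scheme = "family_local", stringsAsFactors = FALSE))
  expect_error(report_substitutions(aln, cat_df), "absent_ref")
})
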