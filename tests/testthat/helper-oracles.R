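# Independent oracles used to validate the implementation. These are
# deliberately naive (exhaustive enumeration, literal set logic) and share
# no code with the package internals.

# Maximum global alignment score by enumerating every alignment path.
# A gap run of length k costs gap_open + (k - 1) * gap_extend; switching
# between gap-in-a and gap-in-b runs starts a new run.
oracle_align_score <- function(a, b, scheme) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  M <- scheme$matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  na <- length(ca)
  nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i == na && j == nb) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i < na && j < nb)
      rec(i + 1L, j + 1L, 0L, sc + M[ca[i + 1L], cb[j + 1L]])
    if (j < nb)  # gap in a
      rec(i, j + 1L, 1L, sc + if (prev == 1L) ge else go)
    if (i < na)  # gap in b
      rec(i + 1L, j, 2L, sc + if (prev == 2L) ge else go)
  }
  rec(0L, 0L, 0L, 0)
  best
}

# Literal reading of the column rule: try every residue, then every group.
oracle_column_label <- function(column, groups, threshold) {
  n <- length(column)
  res <- column[!(column %in% c("-", "X"))]
  id_best <- 0
  for (r in unique(res)) id_best <- max(id_best, sum(res == r) / n)
  grp_best <- 0
  for (g in groups) grp_best <- max(grp_best, sum(res %in% g) / n)
  if (id_best >= threshold) "identical"
  else if (grp_best >= threshold) "conservative"
  else "unconserved"
}

# Independent class-rule table over residues plus gap and X, written as
# explicit per-class membership tests.
oracle_class_rule <- function(r1, r2) {
  amb <- c("-", "X")
  if (r1 %in% amb || r2 %in% amb) return("undetermined")
  first_ok <- list(I = "W", II = c("Y", "F", "L"), III = "W")
  second_ok <- list(I = "W", II = c("Y", "F"), III = c("C", "Y"))
  for (cl in c("I", "II", "III"))
    if (r1 %in% first_ok[[cl]] && r2 %in% second_ok[[cl]]) return(cl)
  "unclassified"
}

ALL_SYMBOLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                 "X", "-")

# Does `tips` form a clade (a split) of the possibly unrooted tree?
is_clade <- function(tree, tips) {
  target <- sort(match(tips, tree$tip.label))
  if (anyNA(target)) stop("tips not in tree")
  all_tips <- seq_along(tree$tip.label)
  if (length(target) <= 1L || length(target) == length(all_tips))
    return(TRUE)
  parts <- ape::prop.part(tree)
  comp <- sort(setdiff(all_tips, target))
  for (p in parts) {
    p <- sort(p)
    if (identical(p, target) || identical(p, comp)) return(TRUE)
  }
  FALSE
}

random_aa_string <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
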