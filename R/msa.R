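#' Scoring scheme for protein alignment
#'
#' Bundles a substitution matrix with affine gap penalties: a gap run of
#' length k costs `gap_open + (k - 1) * gap_extend`. Defaults are the
#' standard protein settings (BLOSUM62, -10 / -0.5); alignment parameters
#' of the original ClustalW runs are not restated anywhere, so all values
#' are configurable.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"PAM250"`), or a numeric matrix with residue
#'   dimnames.
#' @param gap_open,gap_extend Negative penalties with
#'   `gap_open <= gap_extend < 0`.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = -10,
                           gap_extend = -0.5) {
  if (is.character(matrix)) {
    name <- matrix
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    matrix <- get(name, envir = e)
  } else {
    name <- "custom"
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix)))
    stop("scoring_scheme: substitution matrix must have residue dimnames",
         call. = FALSE)
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop("scoring_scheme: need gap_open <= gap_extend < 0", call. = FALSE)
  structure(list(name = name, matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.as_sequences <- function(records) {
  if (inherits(records, "protein_records") || is.data.frame(records))
    setNames(records$sequence, records$id)
  else if (is.character(records)) {
    if (is.null(names(records)))
      names(records) <- paste0("seq", seq_along(records))
    records
  } else stop("expected protein_records or a named character vector",
              call. = FALSE)
}

# Score of aligning a sequence to itself: sum of diagonal matrix entries.
self_align_score <- function(sequence, scheme) {
  chars <- .seq_chars(sequence)
  sum(diag(scheme$matrix[chars, chars, drop = FALSE]))
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment maximizing the substitution
#' score with affine gap costs. The traceback tie-break is fixed
#' (match/mismatch over gap-in-a over gap-in-b), so the output is
#' deterministic.
#'
#' @param a,b Sequences: single-row [protein_records], or plain strings.
#' @param scheme A [scoring_scheme()].
#' @return A list with `alignment` (two-row [aa_alignment]) and `score`.
#' @export
pairwise_align <- function(a, b, scheme = scoring_scheme()) {
  sa <- .as_sequences(a); sb <- .as_sequences(b)
  if (length(sa) != 1L || length(sb) != 1L)
    stop("pairwise_align: expects exactly one sequence on each side",
         call. = FALSE)
  ca <- .seq_chars(sa); cb <- .seq_chars(sb)
  if (!length(ca) || !length(cb))
    stop("pairwise_align: empty sequence", call. = FALSE)
  S <- scheme$matrix[ca, cb, drop = FALSE]
  res <- affine_dp_cpp(S, scheme$gap_open, scheme$gap_extend)
  rows <- .moves_to_rows(res$moves, ca, cb)
  ids <- c(names(sa), names(sb))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  list(alignment = aa_alignment(ids, rows), score = res$score)
}

# moves: 1 diag, 2 gap in a (consume b), 3 gap in b (consume a)
.moves_to_rows <- function(moves, ca, cb) {
  ra <- character(length(moves)); rb <- character(length(moves))
  i <- 0L; j <- 0L
  for (k in seq_along(moves)) {
    mv <- moves[k]
    if (mv == 1L) {
      i <- i + 1L; j <- j + 1L
      ra[k] <- ca[i]; rb[k] <- cb[j]
    } else if (mv == 2L) {
      j <- j + 1L
      ra[k] <- "-"; rb[k] <- cb[j]
    } else {
      i <- i + 1L
      ra[k] <- ca[i]; rb[k] <- "-"
    }
  }
  c(paste(ra, collapse = ""), paste(rb, collapse = ""))
}

#' UPGMA guide tree from pairwise alignment scores
#'
#' Pairwise scores are normalized to distances
#' `1 - score / min(self-scores)` (clamped to \[0, 1\]) and clustered by
#' UPGMA. Ties are joined lowest-input-index first, so the merge order is
#' deterministic.
#'
#' @param records A [protein_records] data frame (>= 2 rows).
#' @param scheme A [scoring_scheme()].
#' @return A list of class `guide_tree` with `labels`, `merge` (hclust
#'   convention: negative entries are leaves), and `height`.
#' @export
guide_tree <- function(records, scheme = scoring_scheme()) {
  seqs <- .as_sequences(records)
  n <- length(seqs)
  if (n < 2L) stop("guide_tree: need >= 2 records", call. = FALSE)
  selfs <- vapply(seqs, self_align_score, 0, scheme = scheme)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- pairwise_align(seqs[i], seqs[j], scheme)$score
      d <- 1 - s / min(selfs[i], selfs[j])
      D[i, j] <- D[j, i] <- min(max(d, 0), 1)
    }
  }
  .upgma(D, names(seqs))
}

# UPGMA with deterministic lowest-index tie-break. Clusters are kept in
# creation order (leaves first); the pair minimizing average-linkage
# distance with the lexicographically smallest (i, j) wins.
.upgma <- function(D, labels) {
  n <- nrow(D)
  active <- seq_len(n)             # cluster ids; 1..n leaves, then merges
  sizes <- rep(1L, n)
  cl2merge <- rep(NA_integer_, n)  # merge row that created cluster, NA = leaf
  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  Dc <- D                          # distance between active clusters
  idx <- seq_len(n)                # position of active clusters in Dc
  for (step in seq_len(n - 1L)) {
    na <- length(active)
    best <- NULL
    for (i in seq_len(na - 1L)) {
      for (j in seq.int(i + 1L, na)) {
        d <- Dc[i, j]
        if (is.null(best) || d < best$d - 1e-12) best <- list(d = d, i = i, j = j)
      }
    }
    i <- best$i; j <- best$j
    mi <- cl2merge[active[i]]; mj <- cl2merge[active[j]]
    merge[step, ] <- c(if (is.na(mi)) -active[i] else mi,
                       if (is.na(mj)) -active[j] else mj)
    height[step] <- best$d / 2
    # average linkage update
    ni <- sizes[active[i]]; nj <- sizes[active[j]]
    newd <- (ni * Dc[i, ] + nj * Dc[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(na), c(i, j))
    Dc <- rbind(cbind(Dc[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    newid <- n + step
    sizes <- c(sizes, ni + nj)
    cl2merge <- c(cl2merge, step)
    active <- c(active[keep], newid)
  }
  structure(list(labels = labels, merge = merge, height = height),
            class = "guide_tree")
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences progressively in guide-tree merge order using
#' profile-profile dynamic programming: the score for pairing two profile
#' columns is the average substitution score over all residue pairs (gaps
#' contribute 0), with the scheme's affine gap penalties. Once a gap is
#' introduced it is never removed ("once a gap, always a gap"). Output
#' rows are returned in input order.
#'
#' @param records A [protein_records] data frame (>= 2 rows).
#' @param scheme A [scoring_scheme()].
#' @return An [aa_alignment].
#' @export
progressive_align <- function(records, scheme = scoring_scheme()) {
  seqs <- .as_sequences(records)
  n <- length(seqs)
  if (n < 2L) stop("progressive_align: need >= 2 records", call. = FALSE)
  gt <- guide_tree(records, scheme)
  # profiles: list of character matrices (members x columns), + member ids
  leaf_profile <- function(k) {
    m <- matrix(.seq_chars(seqs[[k]]), nrow = 1L)
    rownames(m) <- names(seqs)[k]
    m
  }
  profiles <- vector("list", n - 1L)
  fetch <- function(ref) {
    if (ref < 0L) leaf_profile(-ref) else profiles[[ref]]
  }
  for (step in seq_len(n - 1L)) {
    A <- fetch(gt$merge[step, 1L])
    B <- fetch(gt$merge[step, 2L])
    profiles[[step]] <- .merge_profiles(A, B, scheme)
  }
  final <- profiles[[n - 1L]]
  final <- final[match(names(seqs), rownames(final)), , drop = FALSE]
  aa_alignment(names(seqs), apply(final, 1L, paste, collapse = ""))
}

# Profile-profile merge: average-of-pairs column scores via frequency
# vectors, affine DP, then gap-column insertion into both profiles.
.merge_profiles <- function(A, B, scheme) {
  mat <- scheme$matrix
  syms <- rownames(mat)
  freq <- function(P) {
    f <- apply(P, 2L, function(col) {
      col <- col[col != "-"]
      tabulate(match(col, syms), nbins = length(syms))
    })
    matrix(f, nrow = length(syms))
  }
  fA <- freq(A); fB <- freq(B)
  S <- t(fA) %*% mat %*% fB / (nrow(A) * nrow(B))
  res <- affine_dp_cpp(S, scheme$gap_open, scheme$gap_extend)
  moves <- res$moves
  la <- ncol(A); lb <- ncol(B); L <- length(moves)
  outA <- matrix("-", nrow(A), L, dimnames = list(rownames(A), NULL))
  outB <- matrix("-", nrow(B), L, dimnames = list(rownames(B), NULL))
  i <- 0L; j <- 0L
  for (k in seq_len(L)) {
    mv <- moves[k]
    if (mv != 2L) { i <- i + 1L; outA[, k] <- A[, i] }
    if (mv != 3L) { j <- j + 1L; outB[, k] <- B[, j] }
  }
  rbind(outA, outB)
}

#' Sum-of-pairs score of a multiple alignment
#'
#' For every pair of rows the alignment is projected (columns where both
#' rows have gaps dropped) and scored with the substitution matrix plus
#' affine gap costs; the total over all pairs is returned.
#'
#' @param alignment An [aa_alignment].
#' @param scheme A [scoring_scheme()].
#' @return A single number.
#' @export
alignment_sp_score <- function(alignment, scheme = scoring_scheme()) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      total <- total + .score_pair_rows(m[i, ], m[j, ], scheme)
    }
  }
  total
}

.score_pair_rows <- function(ra, rb, scheme) {
  keep <- !(ra == "-" & rb == "-")
  ra <- ra[keep]; rb <- rb[keep]
  sc <- 0
  in_gap <- 0L  # 0 none, 1 gap in a, 2 gap in b
  for (k in seq_along(ra)) {
    if (ra[k] == "-") {
      sc <- sc + if (in_gap == 1L) scheme$gap_extend else scheme$gap_open
      in_gap <- 1L
    } else if (rb[k] == "-") {
      sc <- sc + if (in_gap == 2L) scheme$gap_extend else scheme$gap_open
      in_gap <- 2L
    } else {
      sc <- sc + scheme$matrix[ra[k], rb[k]]
      in_gap <- 0L
    }
  }
  sc
}
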