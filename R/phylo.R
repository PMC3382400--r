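#' Pairwise distance matrix from an alignment
#'
#' p-distance is the fraction of differing residues among comparable
#' sites; a site is comparable for a pair when both rows carry a residue
#' other than `X` (pairwise deletion), or, under complete deletion, when
#' no row of the alignment carries a gap or `X` in that column. The
#' Poisson correction is `d = -ln(1 - p)`.
#'
#' @param alignment An [aa_alignment] with >= 3 rows.
#' @param model `"p_distance"` (default) or `"poisson"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric numeric matrix with row/column names; attributes
#'   `model` and `deletion`.
#' @export
distance_matrix <- function(alignment,
                            model = c("p_distance", "poisson"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  m <- alignment_matrix(alignment)
  if (nrow(m) < 3L)
    stop("distance_matrix: need >= 3 rows", call. = FALSE)
  if (deletion == "complete") {
    keep <- apply(m, 2L, function(col) all(!(col %in% c("-", "X"))))
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !(m[i, ] %in% c("-", "X")) & !(m[j, ] %in% c("-", "X"))
      ncomp <- sum(ok)
      if (ncomp == 0L)
        stop("distance_matrix: no comparable sites between ",
             sQuote(rownames(m)[i]), " and ", sQuote(rownames(m)[j]),
             call. = FALSE)
      p <- sum(m[i, ok] != m[j, ok]) / ncomp
      d <- if (model == "poisson") {
        if (p >= 1)
          stop("distance_matrix: Poisson correction undefined at p = 1 ",
               "for pair ", sQuote(rownames(m)[i]), ", ",
               sQuote(rownames(m)[j]), call. = FALSE)
        -log(1 - p)
      } else p
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "model") <- model
  attr(D, "deletion") <- deletion
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining: repeatedly join the pair (i, j) minimizing
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`, with
#' branch lengths from the standard split formula and the reduced
#' distances `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`. Q-ties are
#' broken by the lowest (i, j) index pair in cluster-creation order, so
#' the output is deterministic. Negative branch lengths are clamped to 0;
#' the raw values are kept in the `negative_lengths` attribute. The
#' result is an unrooted binary tree whose final node is the 3-way join.
#'
#' @param D Symmetric distance matrix with zero diagonal and row names
#'   (>= 3 taxa), e.g. from [distance_matrix()].
#' @return An [ape::as.phylo] `phylo` object (unrooted).
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("neighbor_joining: D must be a square matrix", call. = FALSE)
  if (any(!is.finite(D)))
    stop("neighbor_joining: non-finite distances", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8)
    stop("neighbor_joining: D must be symmetric", call. = FALSE)
  n <- nrow(D)
  if (n < 3L) stop("neighbor_joining: need >= 3 taxa", call. = FALSE)
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))

  nodes <- lapply(ids, function(x) list(label = x))
  Dc <- unname(D)
  neg <- list()
  clamp <- function(len, what) {
    if (len < 0) {
      neg[[length(neg) + 1L]] <<- data.frame(node = what, raw = len)
      0
    } else len
  }

  while (length(nodes) > 3L) {
    na <- length(nodes)
    R <- rowSums(Dc)
    best <- NULL
    for (i in seq_len(na - 1L)) {
      for (j in seq.int(i + 1L, na)) {
        q <- (na - 2) * Dc[i, j] - R[i] - R[j]
        if (is.null(best) || q < best$q - 1e-12)
          best <- list(q = q, i = i, j = j)
      }
    }
    i <- best$i; j <- best$j
    bi <- 0.5 * Dc[i, j] + (R[i] - R[j]) / (2 * (na - 2))
    bj <- Dc[i, j] - bi
    li <- clamp(bi, .node_label(nodes[[i]]))
    lj <- clamp(bj, .node_label(nodes[[j]]))
    newnode <- list(children = list(list(node = nodes[[i]], length = li),
                                    list(node = nodes[[j]], length = lj)))
    keep <- setdiff(seq_len(na), c(i, j))
    newd <- 0.5 * (Dc[i, ] + Dc[j, ] - Dc[i, j])
    Dc <- rbind(cbind(Dc[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    nodes <- c(nodes[keep], list(newnode))
  }

  # final three-way join: closed-form three-point lengths
  d12 <- Dc[1, 2]; d13 <- Dc[1, 3]; d23 <- Dc[2, 3]
  l1 <- clamp((d12 + d13 - d23) / 2, .node_label(nodes[[1L]]))
  l2 <- clamp((d12 + d23 - d13) / 2, .node_label(nodes[[2L]]))
  l3 <- clamp((d13 + d23 - d12) / 2, .node_label(nodes[[3L]]))
  root <- list(children = list(list(node = nodes[[1L]], length = l1),
                               list(node = nodes[[2L]], length = l2),
                               list(node = nodes[[3L]], length = l3)))
  tree <- .nested_to_phylo(root, ids)
  attr(tree, "negative_lengths") <-
    if (length(neg)) do.call(rbind, neg) else
      data.frame(node = character(0), raw = numeric(0))
  tree
}

.node_label <- function(node) {
  if (!is.null(node$label)) node$label else "internal"
}

# Convert a nested (node, length) structure into an ape "phylo" object.
# Tips are numbered in `tip_labels` order, internal nodes in preorder
# starting at n + 1 (root first), as ape expects.
.nested_to_phylo <- function(root, tip_labels) {
  n <- length(tip_labels)
  edges <- list()
  lens <- numeric(0)
  next_internal <- n + 1L
  walk <- function(node, parent_num) {
    if (!is.null(node$label)) return(match(node$label, tip_labels))
    num <- next_internal
    next_internal <<- next_internal + 1L
    for (ch in node$children) {
      child_num <- walk(ch$node, num)
      edges[[length(edges) + 1L]] <<- c(num, child_num)
      lens[length(lens) + 1L] <<- ch$length
    }
    num
  }
  # assign root number first so children edges reference it
  root_num <- next_internal
  next_internal <- next_internal + 1L
  for (ch in root$children) {
    child_num <- walk(ch$node, root_num)
    edges[[length(edges) + 1L]] <- c(root_num, child_num)
    lens[length(lens) + 1L] <- ch$length
  }
  edge <- do.call(rbind, edges)
  tree <- structure(list(edge = edge, edge.length = lens,
                         tip.label = tip_labels,
                         Nnode = next_internal - n - 1L),
                    class = "phylo")
  # walk() numbers internal nodes in preorder but emits each subtree's
  # edges before the edge leading to it; normalize to cladewise order
  ape::reorder.phylo(tree, "cladewise")
}

#' Serialize a tree to Newick
#'
#' Branch lengths are printed with 6 decimal places; child order follows
#' the tree's edge order; whitespace in labels is replaced by `_`.
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; when given the string is also
#'   written there with a trailing newline.
#' @param digits Decimal places for branch lengths (default 6).
#' @return The Newick string (invisibly when `path` is given).
#' @export
to_newick <- function(tree, path = NULL, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  root <- n + 1L
  fmt <- paste0("%.", digits, "f")
  lab <- function(x) gsub("[[:space:]]+", "_", x)
  rec <- function(node) {
    if (node <= n) return(lab(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      paste0(rec(tree$edge[r, 2L]), ":",
             sprintf(fmt, tree$edge.length[r]))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  s <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Write a distance matrix as square TSV
#'
#' First column holds the taxon ids; the header repeats them.
#'
#' @param D Symmetric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(id = rownames(D), as.data.frame(D, check.names = FALSE),
                   check.names = FALSE)
  write_report_tsv(df, path)
}

#' Read a distance matrix from TSV or PHYLIP square format
#'
#' Accepts either the TSV written by [write_distance_tsv()] or a
#' PHYLIP-style square matrix whose first line is the taxon count.
#'
#' @param path Input path.
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_distance_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^[[:space:]]*[0-9]+[[:space:]]*$", first)) {
    n <- as.integer(trimws(first))
    body <- utils::read.table(path, skip = 1L, nrows = n,
                              stringsAsFactors = FALSE)
    ids <- body[[1L]]
    D <- as.matrix(body[, -1L, drop = FALSE])
  } else {
    body <- read.delim(path, check.names = FALSE,
                       stringsAsFactors = FALSE)
    ids <- body[[1L]]
    D <- as.matrix(body[, -1L, drop = FALSE])
  }
  dimnames(D) <- list(ids, ids)
  storage.mode(D) <- "double"
  if (max(abs(D - t(D))) > 1e-8)
    stop("read_distance_tsv: matrix is not symmetric", call. = FALSE)
  D
}
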