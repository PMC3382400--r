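#' The ten conservative-substitution groups
#'
#' The classical amino-acid groups used to call conservative columns in
#' alignment figures: STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW,
#' GA. A residue may belong to several groups; `X` belongs to none.
#'
#' @return A named list of character vectors, in the canonical order used
#'   for tie-breaking.
#' @export
conservative_groups <- function() {
  groups <- list(
    STA  = c("S", "T", "A"),
    NEQK = c("N", "E", "Q", "K"),
    NHQK = c("N", "H", "Q", "K"),
    NDEQ = c("N", "D", "E", "Q"),
    QHRK = c("Q", "H", "R", "K"),
    MILV = c("M", "I", "L", "V"),
    MILF = c("M", "I", "L", "F"),
    HY   = c("H", "Y"),
    FYW  = c("F", "Y", "W"),
    GA   = c("G", "A"))
  groups
}

#' Classify one alignment column
#'
#' A column is `identical` if a single residue occurs in at least
#' `threshold` of ALL rows (gaps and `X` count in the denominator, never
#' the numerator), else `conservative` if one of the groups covers at
#' least `threshold` of all rows, else `unconserved`. Identical takes
#' precedence over conservative; ties between groups are broken by the
#' canonical group order.
#'
#' @param column Character vector of residues/gaps (one per row).
#' @param groups A list of residue groups (default
#'   [conservative_groups()]).
#' @param threshold Fraction of rows required (default 0.70).
#' @return A list with `label` (`identical`, `conservative` or
#'   `unconserved`), `fraction` (supporting fraction of the winner; for
#'   unconserved columns, the best coverage achieved), and `winner` (the
#'   residue or group name, `NA` for unconserved).
#' @export
classify_column <- function(column, groups = conservative_groups(),
                            threshold = 0.70) {
  n <- length(column)
  if (n == 0L) stop("classify_column: empty column", call. = FALSE)
  res <- column[!(column %in% c("-", "X"))]
  res_frac <- 0; res_win <- NA_character_
  if (length(res)) {
    tab <- table(res)
    res_frac <- max(tab) / n
    res_win <- names(tab)[which.max(tab)]
  }
  grp_frac <- 0; grp_win <- NA_character_
  for (g in names(groups)) {
    cov <- sum(res %in% groups[[g]]) / n
    if (cov > grp_frac + 1e-12) { grp_frac <- cov; grp_win <- g }
  }
  if (res_frac >= threshold) {
    list(label = "identical", fraction = res_frac, winner = res_win)
  } else if (grp_frac >= threshold) {
    list(label = "conservative", fraction = grp_frac, winner = grp_win)
  } else {
    list(label = "unconserved", fraction = max(res_frac, grp_frac),
         winner = NA_character_)
  }
}

#' Conservation profile of an alignment
#'
#' Applies [classify_column()] to every column.
#'
#' @param alignment An [aa_alignment].
#' @param groups,threshold Passed to [classify_column()].
#' @return A data frame of class `conservation_profile` with columns
#'   `column`, `label`, `fraction`, `winner`; the per-label counts are
#'   attached as attribute `summary` and the threshold as `threshold`.
#' @export
profile_alignment <- function(alignment, groups = conservative_groups(),
                              threshold = 0.70) {
  m <- alignment_matrix(alignment)
  cols <- lapply(seq_len(ncol(m)), function(j)
    classify_column(m[, j], groups, threshold))
  prof <- data.frame(
    column = seq_len(ncol(m)),
    label = vapply(cols, `[[`, "", "label"),
    fraction = vapply(cols, `[[`, 0, "fraction"),
    winner = vapply(cols, `[[`, "", "winner"),
    stringsAsFactors = FALSE)
  attr(prof, "summary") <- table(factor(prof$label,
    levels = c("identical", "conservative", "unconserved")))
  attr(prof, "threshold") <- threshold
  class(prof) <- c("conservation_profile", "data.frame")
  prof
}

#' Conservation marks line for a profile
#'
#' `*` under identical columns, `.` under conservative columns, space
#' otherwise — the plain-text counterpart of the blue/gray highlighting of
#' published alignment figures.
#'
#' @param profile A [profile_alignment()] result.
#' @return A single string, one character per column.
#' @export
conservation_marks <- function(profile) {
  paste(ifelse(profile$label == "identical", "*",
        ifelse(profile$label == "conservative", ".", " ")), collapse = "")
}

#' Render an alignment as text with conservation marks
#'
#' @param alignment An [aa_alignment].
#' @param profile Optional precomputed profile.
#' @param width Block width (default 60).
#' @return A character vector of lines, invisibly also printable.
#' @export
render_alignment <- function(alignment, profile = NULL, width = 60L) {
  if (is.null(profile)) profile <- profile_alignment(alignment)
  marks <- conservation_marks(profile)
  idw <- max(nchar(alignment$ids)) + 2L
  lines <- character(0)
  for (start in seq(1L, alignment$length, by = width)) {
    end <- min(start + width - 1L, alignment$length)
    for (k in seq_along(alignment$ids))
      lines <- c(lines, sprintf("%-*s%s", idw, alignment$ids[k],
                                substr(alignment$rows[k], start, end)))
    lines <- c(lines, sprintf("%-*s%s", idw, "", substr(marks, start, end)),
               "")
  }
  lines
}

#' Write a conservation profile as TSV
#'
#' Columns, in order: `column`, `label`, `fraction`, `winner`.
#'
#' @param profile A [profile_alignment()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, path) {
  write_report_tsv(profile[, c("column", "label", "fraction", "winner")],
                   path)
}
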