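#' Load a residue-anchor catalog
#'
#' An anchor is a functionally important reference residue: cap-binding
#' tryptophans, eIF4G/4E-BP (scaffold) binding residues, phosphorylation
#' sites, or the two class-diagnostic positions. Positions are 1-based in
#' the ungapped reference sequence; the `scheme` tag records which
#' numbering convention the position follows (mouse_eIF4E, human_eIF4E,
#' dmel_eIF4E1 or family_local), since cross-protein numbering is resolved
#' only through alignment columns, never by offsets.
#'
#' The packaged default catalog carries the reference positions named in
#' the comparative literature: the mouse cap triad Trp-56/Trp-102/Trp-166
#' and phospho Ser-209 (Ser251 in *D. melanogaster* eIF4E-1), the human
#' class-diagnostic Trp-43/Trp-56, and family-local sites of the fly
#' eIF4E-3/-4/-6 and 4E-HP proteins.
#'
#' @param path Path to a TSV with columns `reference_id`, `position`,
#'   `expected`, `role`, `scheme`; `NULL` loads the packaged default.
#' @return An `anchor_catalog` data frame.
#' @export
load_anchor_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "anchor_catalog.tsv",
                        package = "eif4efam", mustWork = TRUE)
  cat_df <- read.delim(path, stringsAsFactors = FALSE)
  as_anchor_catalog(cat_df)
}

#' Validate a data frame as an anchor catalog
#'
#' @param cat_df Data frame with the five catalog columns.
#' @return An `anchor_catalog` data frame.
#' @export
as_anchor_catalog <- function(cat_df) {
  needed <- c("reference_id", "position", "expected", "role", "scheme")
  if (!all(needed %in% names(cat_df)))
    stop("anchor catalog: missing column(s): ",
         paste(setdiff(needed, names(cat_df)), collapse = ", "),
         call. = FALSE)
  roles <- c("cap", "scaffold_binding", "phospho", "class_diagnostic")
  for (k in seq_len(nrow(cat_df))) {
    line <- k + 1L  # header is line 1
    if (is.na(cat_df$position[k]) || cat_df$position[k] < 1 ||
        cat_df$position[k] != round(cat_df$position[k]))
      stop("anchor catalog line ", line, ": position must be a positive ",
           "integer", call. = FALSE)
    if (!cat_df$expected[k] %in% AA20)
      stop("anchor catalog line ", line, ": expected residue ",
           sQuote(cat_df$expected[k]), " is not an amino-acid code",
           call. = FALSE)
    if (!cat_df$role[k] %in% roles)
      stop("anchor catalog line ", line, ": unknown role ",
           sQuote(cat_df$role[k]), call. = FALSE)
  }
  cat_df$position <- as.integer(cat_df$position)
  class(cat_df) <- c("anchor_catalog", "data.frame")
  cat_df
}

#' Map a reference anchor through an alignment into a target row
#'
#' Locates the alignment column holding the reference's ungapped
#' `position` and reads off the target row's symbol there; when the
#' target carries a residue at that column, its own 1-based ungapped
#' position is returned too.
#'
#' @param alignment An [aa_alignment] containing both rows.
#' @param anchor A single-row anchor (list or `anchor_catalog` row) with
#'   at least `reference_id` and `position`.
#' @param target_id Row id to map into.
#' @return A list with `observed` (residue or `"-"`), `target_position`
#'   (integer or `NA` when the target is gapped there) and `column`.
#' @export
map_anchor <- function(alignment, anchor, target_id) {
  ref_id <- anchor$reference_id
  ri <- match(ref_id, alignment$ids)
  ti <- match(target_id, alignment$ids)
  if (is.na(ri))
    stop("map_anchor: reference row ", sQuote(ref_id),
         " not in alignment", call. = FALSE)
  if (is.na(ti))
    stop("map_anchor: target row ", sQuote(target_id),
         " not in alignment", call. = FALSE)
  cols <- res2col(alignment$rows[ri])
  if (anchor$position > length(cols))
    stop("map_anchor: position ", anchor$position,
         " beyond reference ", sQuote(ref_id), " (", length(cols),
         " residues)", call. = FALSE)
  col <- cols[anchor$position]
  tchars <- .seq_chars(alignment$rows[ti])
  obs <- tchars[col]
  tpos <- if (obs == "-") NA_integer_ else sum(tchars[seq_len(col)] != "-")
  list(observed = obs, target_position = tpos, column = col)
}

#' Report anchor substitution status across all alignment rows
#'
#' For every (sequence, anchor) pair the observed residue at the mapped
#' column is classified: `conserved` (equal to the expected residue),
#' `conservative_substitution` (shares a conservative group),
#' `nonconservative`, `deleted` (gap at the mapped column) or
#' `undetermined` (`X`).
#'
#' @param alignment An [aa_alignment]; every anchor's `reference_id` must
#'   be a row.
#' @param catalog An `anchor_catalog`.
#' @param groups Conservative groups (default [conservative_groups()]).
#' @return A data frame of class `substitution_report` with columns
#'   `sequence_id`, `reference_id`, `position`, `scheme`, `role`,
#'   `expected`, `observed`, `target_position`, `status`.
#' @export
report_substitutions <- function(alignment, catalog,
                                 groups = conservative_groups()) {
  stopifnot(inherits(alignment, "aa_alignment"))
  missing_refs <- setdiff(unique(catalog$reference_id), alignment$ids)
  if (length(missing_refs))
    stop("report_substitutions: reference row(s) not in alignment for ",
         "anchor(s): ", paste(sQuote(missing_refs), collapse = ", "),
         call. = FALSE)
  out <- list()
  for (k in seq_len(nrow(catalog))) {
    anc <- catalog[k, ]
    for (id in alignment$ids) {
      mp <- map_anchor(alignment, anc, id)
      out[[length(out) + 1L]] <- data.frame(
        sequence_id = id, reference_id = anc$reference_id,
        position = anc$position, scheme = anc$scheme, role = anc$role,
        expected = anc$expected, observed = mp$observed,
        target_position = mp$target_position,
        status = substitution_status(anc$expected, mp$observed, groups),
        stringsAsFactors = FALSE)
    }
  }
  rep_df <- do.call(rbind, out)
  rownames(rep_df) <- NULL
  class(rep_df) <- c("substitution_report", "data.frame")
  rep_df
}

#' Status of one observed residue against an expected anchor residue
#'
#' @param expected Expected single residue.
#' @param observed Observed symbol (residue, `-` or `X`).
#' @param groups Conservative groups.
#' @return One of `conserved`, `conservative_substitution`,
#'   `nonconservative`, `deleted`, `undetermined`.
#' @export
substitution_status <- function(expected, observed,
                                groups = conservative_groups()) {
  if (observed == "-") return("deleted")
  if (observed == "X") return("undetermined")
  if (observed == expected) return("conserved")
  shared <- any(vapply(groups, function(g)
    expected %in% g && observed %in% g, NA))
  if (shared) "conservative_substitution" else "nonconservative"
}

#' Write a substitution report as TSV
#'
#' @param report A [report_substitutions()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_substitution_tsv <- function(report, path) {
  write_report_tsv(report, path)
}
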