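#' Assign an eIF4E class from the two diagnostic residues
#'
#' eIF4E subfamilies are defined by the residues homologous to human eIF4E
#' Trp-43 and Trp-56: Class I carries Trp at both positions; Class II
#' carries Tyr, Phe or Leu at the first and Tyr or Phe at the second;
#' Class III carries Trp at the first and Cys or Tyr at the second. The
#' three classes are disjoint (in particular W/Y is Class III, not II,
#' since W is not in \{Y, F, L\}). A gap or `X` at either position gives
#' `undetermined`; any other combination is `unclassified`.
#'
#' @param residue_1,residue_2 Single symbols (residue, `-` or `X`);
#'   vectorized.
#' @return Character vector over `I`, `II`, `III`, `unclassified`,
#'   `undetermined`.
#' @export
assign_class <- function(residue_1, residue_2) {
  mapply(function(r1, r2) {
    if (r1 %in% c("-", "X") || r2 %in% c("-", "X")) return("undetermined")
    if (r1 == "W" && r2 == "W") return("I")
    if (r1 %in% c("Y", "F", "L") && r2 %in% c("Y", "F")) return("II")
    if (r1 == "W" && r2 %in% c("C", "Y")) return("III")
    "unclassified"
  }, toupper(residue_1), toupper(residue_2), USE.NAMES = FALSE)
}

#' Classify every row of an alignment
#'
#' Extracts the residues at the two class-diagnostic anchor columns (via
#' [map_anchor()]) for every row and applies [assign_class()].
#'
#' @param alignment An [aa_alignment] containing the class-diagnostic
#'   anchors' reference row.
#' @param catalog An `anchor_catalog` with two anchors of role
#'   `class_diagnostic` whose `reference_id` is an alignment row.
#' @param strict Drop rows whose ungapped sequence does not start with
#'   Met before classifying (mirrors the exclusion of partial proteins
#'   missing the start methionine). Default FALSE.
#' @return A data frame of class `class_assignment` with columns `id`,
#'   `residue_1`, `residue_2`, `eif4e_class`; per-class counts attached
#'   as attribute `summary`.
#' @export
classify_family <- function(alignment, catalog, strict = FALSE) {
  stopifnot(inherits(alignment, "aa_alignment"))
  diag <- catalog[catalog$role == "class_diagnostic", , drop = FALSE]
  diag <- diag[diag$reference_id %in% alignment$ids, , drop = FALSE]
  if (nrow(diag) < 2L)
    stop("classify_family: configuration error: need two class_diagnostic ",
         "anchors with their reference row in the alignment", call. = FALSE)
  ref <- diag$reference_id[1L]
  diag <- diag[diag$reference_id == ref, , drop = FALSE]
  if (nrow(diag) != 2L)
    stop("classify_family: configuration error: expected exactly two ",
         "class_diagnostic anchors for reference ", sQuote(ref),
         call. = FALSE)
  diag <- diag[order(diag$position), , drop = FALSE]
  ids <- alignment$ids
  if (strict) {
    starts_m <- startsWith(ungap(alignment$rows), "M")
    ids <- ids[starts_m[match(ids, alignment$ids)]]
  }
  r1 <- vapply(ids, function(id)
    map_anchor(alignment, diag[1L, ], id)$observed, "")
  r2 <- vapply(ids, function(id)
    map_anchor(alignment, diag[2L, ], id)$observed, "")
  out <- data.frame(id = ids, residue_1 = unname(r1),
                    residue_2 = unname(r2),
                    eif4e_class = assign_class(r1, r2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- table(factor(out$eif4e_class,
    levels = c("I", "II", "III", "unclassified", "undetermined")))
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Cross-check sequence-derived classes against inventory labels
#'
#' Joins class assignments with inventory `class_label`s by id and reports
#' mismatches; nothing is silently corrected.
#'
#' @param assignments A [classify_family()] result.
#' @param inventory An inventory with `identifier` and `class_label`.
#' @return Data frame of mismatching rows (possibly empty) with columns
#'   `id`, `eif4e_class`, `class_label`.
#' @export
crosscheck_classes <- function(assignments, inventory) {
  m <- merge(assignments, inventory[, c("identifier", "class_label")],
             by.x = "id", by.y = "identifier")
  m[!is.na(m$class_label) & m$eif4e_class != m$class_label,
    c("id", "eif4e_class", "class_label")]
}

#' Write class assignments as TSV
#'
#' Columns, in order: `id`, `residue_1`, `residue_2`, `eif4e_class`.
#'
#' @param assignments A [classify_family()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_classes_tsv <- function(assignments, path) {
  write_report_tsv(assignments, path)
}
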