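#' Construct a set of protein records
#'
#' A protein record holds one ungapped amino-acid sequence together with
#' its species and gene-family labels (e.g. `"eIF4E-1"`, `"4E-HP"`).
#' Records are stored as a data frame with class `protein_records`.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param sequence Character vector of ungapped sequences over the 20
#'   amino-acid one-letter codes plus `X` (ambiguity). Lower case input is
#'   uppercased.
#' @param species,family Optional character vectors (recycled).
#' @param description Optional free-text description (recycled).
#' @return A `protein_records` data frame with columns `id`, `species`,
#'   `family`, `sequence`, `description`.
#' @export
protein_records <- function(id, sequence, species = NA_character_,
                            family = NA_character_, description = "") {
  rec <- data.frame(id = as.character(id),
                    species = as.character(species),
                    family = as.character(family),
                    sequence = toupper(as.character(sequence)),
                    description = as.character(description),
                    stringsAsFactors = FALSE)
  class(rec) <- c("protein_records", "data.frame")
  validate_protein_records(rec)
  rec
}

validate_protein_records <- function(rec) {
  if (nrow(rec) == 0L)
    stop("protein_records: no records", call. = FALSE)
  if (anyDuplicated(rec$id))
    stop("protein_records: duplicate sequence id(s): ",
         paste(sQuote(unique(rec$id[duplicated(rec$id)])), collapse = ", "),
         call. = FALSE)
  for (k in seq_len(nrow(rec))) {
    s <- rec$sequence[k]
    if (nchar(s) == 0L)
      stop("protein_records: empty sequence for record ", sQuote(rec$id[k]),
           call. = FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    bad <- unique(chars[!.aa_ok(chars)])
    if (length(bad))
      stop("protein_records: illegal character(s) ",
           paste(sQuote(bad), collapse = ", "), " in record ",
           sQuote(rec$id[k]), call. = FALSE)
  }
  invisible(rec)
}

# Header dialect: "id species=<token> family=<token> <free text>".
# Values are single whitespace-free tokens; everything unannotated is kept
# in `description`.
.parse_header <- function(header) {
  tokens <- strsplit(trimws(header), "[[:space:]]+")[[1L]]
  id <- tokens[1L]
  species <- NA_character_
  family <- NA_character_
  desc <- character(0)
  for (tok in tokens[-1L]) {
    if (startsWith(tok, "species=")) {
      species <- sub("^species=", "", tok)
    } else if (startsWith(tok, "family=")) {
      family <- sub("^family=", "", tok)
    } else {
      desc <- c(desc, tok)
    }
  }
  list(id = id, species = species, family = family,
       description = paste(desc, collapse = " "))
}

.format_header <- function(rec) {
  safe <- function(x) gsub("[[:space:]]+", "_", x)
  h <- rec$id
  if (!is.na(rec$species) && nzchar(rec$species))
    h <- paste0(h, " species=", safe(rec$species))
  if (!is.na(rec$family) && nzchar(rec$family))
    h <- paste0(h, " family=", safe(rec$family))
  if (!is.na(rec$description) && nzchar(rec$description))
    h <- paste(h, rec$description)
  h
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased on read and validated against the amino-acid
#' alphabet (plus `X`). Headers are parsed as
#' `id species=<token> family=<token>` with any unannotated tokens kept in
#' the description.
#'
#' @param path Path to a FASTA file.
#' @return A [protein_records] data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("read_fasta: file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("read_fasta: no sequences in ", path, call. = FALSE)
  parsed <- lapply(names(set), .parse_header)
  rec <- data.frame(id = vapply(parsed, `[[`, "", "id"),
                    species = vapply(parsed, `[[`, "", "species"),
                    family = vapply(parsed, `[[`, "", "family"),
                    sequence = toupper(as.character(set)),
                    description = vapply(parsed, `[[`, "", "description"),
                    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  class(rec) <- c("protein_records", "data.frame")
  validate_protein_records(rec)
  rec
}

#' Write protein records to FASTA
#'
#' Lines wrap at 60 columns. Species and family labels are emitted as
#' `species=`/`family=` header tokens (internal whitespace replaced by
#' `_` so that [read_fasta()] round-trips).
#'
#' @param records A [protein_records] data frame.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  validate_protein_records(records)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- vapply(seq_len(nrow(records)),
                       function(k) .format_header(records[k, ]), "")
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Construct a gapped amino-acid alignment
#'
#' All rows must have equal length; removing the `-` gap characters from a
#' row recovers the source sequence exactly.
#'
#' @param ids Character vector of unique row identifiers.
#' @param rows Character vector of equal-length gapped sequences.
#' @return An object of class `aa_alignment` with elements `ids`, `rows`
#'   and `length` (number of columns).
#' @export
aa_alignment <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows))
    stop("aa_alignment: ids and rows differ in length", call. = FALSE)
  if (length(rows) == 0L)
    stop("aa_alignment: no rows", call. = FALSE)
  if (anyDuplicated(ids))
    stop("aa_alignment: duplicate row id(s): ",
         paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", "),
         call. = FALSE)
  len <- nchar(rows)
  if (length(unique(len)) != 1L) {
    stop("aa_alignment: ragged rows; shortest ",
         sQuote(ids[which.min(len)]), " (", min(len), " cols), longest ",
         sQuote(ids[which.max(len)]), " (", max(len), " cols)",
         call. = FALSE)
  }
  for (k in seq_along(rows)) {
    chars <- strsplit(rows[k], "", fixed = TRUE)[[1L]]
    bad <- unique(chars[!.aa_ok(chars, allow_gap = TRUE)])
    if (length(bad))
      stop("aa_alignment: illegal character(s) ",
           paste(sQuote(bad), collapse = ", "), " in row ", sQuote(ids[k]),
           call. = FALSE)
  }
  structure(list(ids = ids, rows = rows, length = unique(len)),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment: ", length(x$ids), " rows x ", x$length, " columns\n",
      sep = "")
  show <- utils::head(seq_along(x$ids), 6L)
  w <- min(x$length, 60L)
  for (k in show)
    cat(sprintf("  %-20s %s%s\n", x$ids[k], substr(x$rows[k], 1L, w),
                if (x$length > w) "..." else ""))
  if (length(x$ids) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @return An [aa_alignment].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path))
    stop("read_alignment: file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("read_alignment: no sequences in ", path, call. = FALSE)
  ids <- vapply(names(set), function(h) .parse_header(h)$id, "",
                USE.NAMES = FALSE)
  aa_alignment(ids, as.character(set))
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment An [aa_alignment].
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(alignment, path, width = 60L) {
  stopifnot(inherits(alignment, "aa_alignment"))
  set <- Biostrings::BStringSet(alignment$rows)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Remove gaps from a gapped sequence
#'
#' @param x Character vector of gapped sequences.
#' @return Character vector with all `-` removed.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# Character matrix view of an alignment (rows x columns).
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  rownames(m) <- alignment$ids
  m
}

# Columns occupied by the k-th residue of a row: res2col(row)[p] is the
# 1-based alignment column holding ungapped position p.
res2col <- function(gapped_row) {
  which(strsplit(gapped_row, "", fixed = TRUE)[[1L]] != "-")
}

#' Load the packaged gene-inventory table
#'
#' The packaged fixture transcribes the published overview of annotated
#' eIF4E-family genes across twelve Drosophila genomes and other insect
#' genomes: one row per (gene family, species) with its database
#' identifier, eIF4E class, and isoform count (2 only for the
#' *D. melanogaster* eIF4E-1/2 gene, whose single gene encodes the eIF4E-1
#' and eIF4E-2 isoforms by alternative splicing).
#'
#' @param path Optional path to an alternative inventory TSV with columns
#'   `gene_family`, `species`, `identifier`, `class_label`,
#'   `isoform_count`.
#' @return An `inventory` data frame.
#' @export
load_inventory <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_inventory.tsv",
                        package = "eif4efam", mustWork = TRUE)
  inv <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_family", "species", "identifier", "class_label",
              "isoform_count")
  if (!all(needed %in% names(inv)))
    stop("load_inventory: missing column(s): ",
         paste(setdiff(needed, names(inv)), collapse = ", "), call. = FALSE)
  key <- paste(inv$gene_family, inv$species)
  if (anyDuplicated(key))
    stop("load_inventory: duplicate (gene_family, species): ",
         paste(sQuote(unique(key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  if (!all((inv$class_label == "II") == (inv$gene_family == "4E-HP")))
    stop("load_inventory: class II must coincide with 4E-HP rows",
         call. = FALSE)
  if (any(inv$isoform_count < 1L))
    stop("load_inventory: isoform_count must be positive", call. = FALSE)
  class(inv) <- c("inventory", "data.frame")
  inv
}

#' Summarize the gene inventory
#'
#' Computes, purely from the inventory table: per-species Class I gene and
#' member counts for the Drosophila genomes, the genus-wide totals, the
#' count of Class I orthologs outside Drosophila (per family and per
#' genome), per-species 4E-HP copy numbers, and the total *D. melanogaster*
#' gene count. With `count_isoforms`, a gene contributes `isoform_count`
#' members but always one gene (the *D. melanogaster* eIF4E-1/2 gene
#' counts 2 members, 1 gene).
#'
#' @param inventory An inventory from [load_inventory()].
#' @param count_isoforms Count isoforms toward member totals (default TRUE).
#' @return A list of class `inventory_summary` with components
#'   `class1_by_species`, `class1_genes_total`, `class1_members_total`,
#'   `non_drosophila_class1` (per family), `class1_per_other_genome`,
#'   `fourehp_by_species`, `dmel_gene_count`.
#' @export
summarize_inventory <- function(inventory, count_isoforms = TRUE) {
  stopifnot(inherits(inventory, "data.frame"))
  is_dros <- startsWith(inventory$species, "D. ")
  c1 <- inventory[inventory$class_label == "I", ]
  c1d <- c1[startsWith(c1$species, "D. "), ]
  c1o <- c1[!startsWith(c1$species, "D. "), ]

  members <- function(df) {
    if (count_isoforms) sum(df$isoform_count) else nrow(df)
  }
  sp <- sort(unique(c1d$species))
  by_sp <- data.frame(
    species = sp,
    genes = vapply(sp, function(s) nrow(c1d[c1d$species == s, ]), 0L),
    members = vapply(sp, function(s) members(c1d[c1d$species == s, ]), 0),
    row.names = NULL, stringsAsFactors = FALSE)

  hp <- inventory[inventory$gene_family == "4E-HP" & is_dros, ]
  hp_sp <- sort(unique(hp$species))
  fourehp <- data.frame(
    species = hp_sp,
    copies = vapply(hp_sp, function(s) nrow(hp[hp$species == s, ]), 0L),
    row.names = NULL, stringsAsFactors = FALSE)

  fam <- sort(unique(c1o$gene_family))
  nondros <- data.frame(
    gene_family = fam,
    orthologs = vapply(fam, function(f) nrow(c1o[c1o$gene_family == f, ]), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  osp <- sort(unique(c1o$species))
  per_other <- data.frame(
    species = osp,
    genes = vapply(osp, function(s) nrow(c1o[c1o$species == s, ]), 0L),
    row.names = NULL, stringsAsFactors = FALSE)

  out <- list(
    class1_by_species = by_sp,
    class1_genes_total = nrow(c1d),
    class1_members_total = members(c1d),
    non_drosophila_class1 = nondros,
    class1_per_other_genome = per_other,
    fourehp_by_species = fourehp,
    dmel_gene_count = nrow(inventory[inventory$species == "D. melanogaster", ]))
  class(out) <- "inventory_summary"
  out
}

#' @export
print.inventory_summary <- function(x, ...) {
  cat("Class I (Drosophila): ", x$class1_genes_total, " genes, ",
      x$class1_members_total, " members\n", sep = "")
  cat("Class I orthologs outside Drosophila: ",
      sum(x$non_drosophila_class1$orthologs), "\n", sep = "")
  cat("D. melanogaster genes (all families): ", x$dmel_gene_count, "\n",
      sep = "")
  cat("\nPer-species Class I gene counts:\n")
  print(x$class1_by_species, row.names = FALSE)
  invisible(x)
}

# Shared TSV writer: fixed column order, no quoting, tab separated.
write_report_tsv <- function(df, path) {
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
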