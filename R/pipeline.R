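#' Pipeline configuration
#'
#' @param fasta Path to the input FASTA of protein sequences.
#' @param out_dir Output directory for the report bundle.
#' @param anchor_catalog Path to an anchor-catalog TSV, or `NULL` for the
#'   packaged default.
#' @param scheme A [scoring_scheme()].
#' @param threshold Conservation threshold in (0, 1] (default 0.70).
#' @param distance_model `"p_distance"` or `"poisson"`.
#' @param inventory Path to an inventory TSV, or `NULL` for the packaged
#'   transcription.
#' @param seed Integer seed echoed into the manifest (the pipeline stages
#'   themselves are deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, out_dir, anchor_catalog = NULL,
                            scheme = scoring_scheme(), threshold = 0.70,
                            distance_model = "p_distance",
                            inventory = NULL, seed = 1L) {
  if (!file.exists(fasta))
    stop("pipeline_config: input FASTA not found: ", fasta, call. = FALSE)
  if (!is.null(anchor_catalog) && !file.exists(anchor_catalog))
    stop("pipeline_config: anchor catalog not found: ", anchor_catalog,
         call. = FALSE)
  if (!is.null(inventory) && !file.exists(inventory))
    stop("pipeline_config: inventory not found: ", inventory,
         call. = FALSE)
  if (!(threshold > 0 && threshold <= 1))
    stop("pipeline_config: threshold must be in (0, 1]", call. = FALSE)
  structure(list(fasta = fasta, out_dir = out_dir,
                 anchor_catalog = anchor_catalog, scheme = scheme,
                 threshold = threshold, distance_model = distance_model,
                 inventory = inventory, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full comparative-analysis pipeline
#'
#' Reads the sequences, builds the progressive multiple alignment, the
#' conservation profile, the anchor substitution report, the class
#' assignments, the neighbor-joining phylogram and the inventory summary,
#' and writes everything to `out_dir` together with a run manifest. A
#' failing stage aborts with the stage name; partial outputs are kept and
#' a `FAILED` marker names the stage and cause.
#'
#' Anchors whose reference row is absent from the input are skipped with
#' a note in the manifest (the packaged catalog references mouse/human
#' numbering rows that a purely insect data set will not contain); the
#' classification stage likewise requires class-diagnostic anchors
#' anchored on an input row.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("run_pipeline: cannot create output directory ", out_dir,
         call. = FALSE)
  notes <- character(0)
  failed <- file.path(out_dir, "FAILED")
  if (file.exists(failed)) file.remove(failed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste("stage:", name), paste("cause:",
                                                conditionMessage(e))),
                 failed)
      stop("run_pipeline: stage ", sQuote(name), " failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  catalog <- stage("configure", load_anchor_catalog(config$anchor_catalog))
  records <- stage("read", read_fasta(config$fasta))

  aln <- stage("align", progressive_align(records, config$scheme))
  write_alignment(aln, file.path(out_dir, "alignment.fasta"))

  prof <- stage("conserve",
                profile_alignment(aln, threshold = config$threshold))
  write_profile_tsv(prof, file.path(out_dir, "conservation.tsv"))

  usable <- catalog[catalog$reference_id %in% aln$ids, , drop = FALSE]
  if (nrow(usable)) {
    subs <- stage("anchors", report_substitutions(aln, usable))
  } else {
    subs <- NULL
    notes <- c(notes, "anchors: no catalog reference row in input; stage skipped")
  }
  if (!is.null(subs))
    write_substitution_tsv(subs, file.path(out_dir, "substitutions.tsv"))

  has_diag <- any(usable$role == "class_diagnostic")
  if (has_diag) {
    classes <- stage("classify", classify_family(aln, usable))
    write_classes_tsv(classes, file.path(out_dir, "classes.tsv"))
  } else {
    classes <- NULL
    notes <- c(notes,
               "classify: no class_diagnostic anchor on an input row; stage skipped")
  }

  tree <- NULL
  if (length(aln$ids) >= 3L) {
    tree <- stage("tree", {
      D <- distance_matrix(aln, model = config$distance_model)
      write_distance_tsv(D, file.path(out_dir, "distances.tsv"))
      neighbor_joining(D)
    })
    to_newick(tree, path = file.path(out_dir, "tree.nwk"))
  } else {
    notes <- c(notes, "tree: fewer than 3 sequences; stage skipped")
  }

  summ <- stage("summarize", {
    inv <- load_inventory(config$inventory)
    summarize_inventory(inv)
  })
  write_report_tsv(summ$class1_by_species,
                   file.path(out_dir, "inventory_summary.tsv"))

  manifest <- c(
    paste("package: eif4efam", as.character(packageVersion("eif4efam"))),
    paste("r_version:", R.version.string),
    paste("input_fasta:", config$fasta),
    paste("n_sequences:", nrow(records)),
    paste("scoring:", config$scheme$name, "gap_open",
          config$scheme$gap_open, "gap_extend", config$scheme$gap_extend),
    paste("threshold:", config$threshold),
    paste("distance_model:", config$distance_model),
    paste("seed:", config$seed),
    paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (length(notes)) paste("note:", notes) else "note: none")
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(records = records, alignment = aln, profile = prof,
                 substitutions = subs, classes = classes, tree = tree,
                 inventory_summary = summ, out_dir = out_dir))
}
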