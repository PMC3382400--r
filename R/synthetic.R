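#' Default synthetic family layout
#'
#' Three families on a shared species tree: two Class I families carrying
#' the diagnostic Trp/Trp pair (mirroring eIF4E-1 and eIF4E-3) and one
#' Class II family carrying Tyr/Phe (mirroring 4E-HP).
#'
#' @return List of family descriptors (`name`, `class_label`,
#'   `diagnostic` pair).
#' @export
default_families <- function() {
  list(list(name = "eIF4E-1", class_label = "I", diagnostic = c("W", "W")),
       list(name = "eIF4E-3", class_label = "I", diagnostic = c("W", "W")),
       list(name = "4E-HP", class_label = "II", diagnostic = c("Y", "F")))
}

#' Configuration for the synthetic eIF4E-family simulator
#'
#' The simulator emulates the statistical structure of real eIF4E
#' ortholog families: paralog families that diverged before the species
#' radiation (so each family is monophyletic by construction), a
#' conserved core with slowly evolving functional "anchor" sites carrying
#' class-diagnostic residues, and length-variable N-terminal extensions
#' (indels occur only there, keeping the core alignment truth
#' unambiguous).
#'
#' @param seed Integer RNG seed; every output is a pure function of the
#'   configuration.
#' @param n_species Number of species (>= 2).
#' @param families List of family descriptors as in [default_families()];
#'   each diagnostic pair must be consistent with its declared class
#'   under [assign_class()].
#' @param core_length Length of the evolving core (>= 60 so that the
#'   diagnostic positions 43 and 56 fit; default 120).
#' @param variable_nterm_max Maximum random N-terminal extension per
#'   lineage (default 20; 0 disables).
#' @param rate Expected substitutions per site per unit branch length at
#'   background sites (default 0.05).
#' @param anchor_rate_multiplier Rate multiplier in \[0, 1\] for anchor
#'   sites (0 freezes them; default 0.1).
#' @param birth_rate Pure-birth rate for the random species tree
#'   (default 1); the tree is rescaled to unit depth.
#' @param tree_newick Optional fixed species tree (Newick string),
#'   returned verbatim by [sample_tree()] instead of a random tree.
#' @param n_anchor_sites Number of additional anchor sites beyond the two
#'   diagnostic positions (default 10).
#' @param family_divergence Expected substitutions per background site on
#'   each family's duplication stem (default 0.4, so two families differ
#'   by twice that — about 45-50% core identity, comparable to real
#'   eIF4E paralog families); the stem predates the species root, so
#'   families diverge before species.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 5L,
                       families = default_families(),
                       core_length = 120L, variable_nterm_max = 20L,
                       rate = 0.05, anchor_rate_multiplier = 0.1,
                       birth_rate = 1, tree_newick = NULL,
                       n_anchor_sites = 10L, family_divergence = 0.4) {
  if (length(families) == 0L)
    stop("sim_config: empty family list", call. = FALSE)
  if (n_species < 2L) stop("sim_config: n_species >= 2", call. = FALSE)
  if (core_length < 60L)
    stop("sim_config: core_length must be >= 60", call. = FALSE)
  if (rate < 0 || family_divergence < 0 || birth_rate <= 0)
    stop("sim_config: rates must be non-negative", call. = FALSE)
  if (anchor_rate_multiplier < 0 || anchor_rate_multiplier > 1)
    stop("sim_config: anchor_rate_multiplier must be in [0, 1]",
         call. = FALSE)
  for (fam in families) {
    if (!all(c("name", "class_label", "diagnostic") %in% names(fam)))
      stop("sim_config: family needs name, class_label, diagnostic",
           call. = FALSE)
    got <- assign_class(fam$diagnostic[1L], fam$diagnostic[2L])
    if (got != fam$class_label)
      stop("sim_config: family ", sQuote(fam$name), " declares class ",
           fam$class_label, " but its diagnostic pair implies ", got,
           call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              families = families, core_length = as.integer(core_length),
              variable_nterm_max = as.integer(variable_nterm_max),
              rate = rate,
              anchor_rate_multiplier = anchor_rate_multiplier,
              birth_rate = birth_rate, tree_newick = tree_newick,
              n_anchor_sites = as.integer(n_anchor_sites),
              family_divergence = family_divergence)
  cfg$diag_positions <- c(43L, 56L)
  cfg$anchor_positions <- .anchor_positions(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# Evenly spaced anchor sites over the core, avoiding the two diagnostic
# positions (which evolve at anchor rate as well).
.anchor_positions <- function(cfg) {
  cand <- unique(round(seq(5, cfg$core_length - 4,
                           length.out = cfg$n_anchor_sites + 2L)))
  cand <- setdiff(cand, cfg$diag_positions)
  as.integer(utils::head(cand, cfg$n_anchor_sites))
}

#' Sample (or load) the species tree
#'
#' A pure-birth tree with `n_species` tips rescaled to unit depth, or the
#' configured fixed Newick tree verbatim. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return An `ape` `phylo` object with tip labels `sp01`, `sp02`, ...
#'   (fixed trees keep their own labels).
#' @export
sample_tree <- function(config) {
  set.seed(config$seed)
  .sample_tree(config)
}

.sample_tree <- function(config) {
  if (!is.null(config$tree_newick))
    return(ape::read.tree(text = config$tree_newick))
  tr <- ape::rphylo(config$n_species, birth = config$birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
  tr
}

.random_core <- function(config) sample(AA20, config$core_length,
                                        replace = TRUE)

# Mutate core characters: independent per-site substitution to a uniform
# different residue, background probability p_bg, anchor (and diagnostic)
# sites probability p_anchor.
.mutate_core <- function(chars, p_bg, p_anchor, config) {
  anchor_idx <- c(config$anchor_positions, config$diag_positions)
  p <- rep(p_bg, length(chars))
  p[anchor_idx] <- p_anchor
  hit <- stats::runif(length(chars)) < p
  for (k in which(hit)) chars[k] <- sample(setdiff(AA20, chars[k]), 1L)
  chars
}

.psub <- function(rate, len) 1 - exp(-rate * len)

#' Evolve one family along the species tree
#'
#' The family ancestor is derived from a shared base ancestor by a
#' duplication-stem mutation (divergence `family_divergence`, predating
#' the species root) with the family's diagnostic residue pair planted at
#' core positions 43 and 56. The core then evolves along the tree under
#' independent per-site substitutions (anchor sites at
#' `rate * anchor_rate_multiplier`); each tip lineage finally gains a
#' random-length, random-residue N-terminal extension.
#'
#' @param tree Species tree (`phylo`) with branch lengths.
#' @param config A [sim_config()].
#' @param family One family descriptor (see [default_families()]).
#' @param family_index Index used to decorrelate the RNG stream between
#'   families when called standalone (default 1).
#' @return A list with `records` ([protein_records]), `truth`
#'   (per-sequence truth rows) and `anchor_truth` (per-anchor residue
#'   states).
#' @export
evolve_family <- function(tree, config, family, family_index = 1L) {
  set.seed(config$seed)
  base <- .random_core(config)
  set.seed(config$seed + 131L * family_index)
  .evolve_family(tree, config, family, base)
}

.evolve_family <- function(tree, config, family, base) {
  mult <- config$anchor_rate_multiplier
  anc <- .mutate_core(base, .psub(1, config$family_divergence),
                      .psub(mult, config$family_divergence), config)
  anc[config$diag_positions] <- family$diagnostic

  n <- length(tree$tip.label)
  root <- n + 1L
  seqs <- vector("list", n)
  recurse <- function(node, chars) {
    rows <- which(tree$edge[, 1L] == node)
    for (r in rows) {
      child <- tree$edge[r, 2L]
      len <- tree$edge.length[r]
      mutated <- .mutate_core(chars, .psub(config$rate, len),
                              .psub(config$rate * mult, len), config)
      if (child <= n) seqs[[child]] <<- mutated
      else recurse(child, mutated)
    }
  }
  recurse(root, anc)

  records <- list()
  truth <- list()
  anchor_truth <- list()
  for (k in seq_len(n)) {
    tip <- tree$tip.label[k]
    nterm_len <- if (config$variable_nterm_max > 0L)
      sample.int(config$variable_nterm_max + 1L, 1L) - 1L else 0L
    nterm <- if (nterm_len > 0L) sample(AA20, nterm_len, replace = TRUE)
             else character(0)
    chars <- c(nterm, seqs[[k]])
    id <- paste(family$name, tip, sep = "_")
    records[[k]] <- data.frame(
      id = id, species = tip, family = family$name,
      sequence = paste(chars, collapse = ""), description = "synthetic",
      stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(
      id = id, species = tip, family = family$name,
      class_label = family$class_label, nterm_length = nterm_len,
      diag1_pos = nterm_len + config$diag_positions[1L],
      diag2_pos = nterm_len + config$diag_positions[2L],
      length = length(chars), stringsAsFactors = FALSE)
    anchor_truth[[k]] <- data.frame(
      id = id, core_position = config$anchor_positions,
      position = nterm_len + config$anchor_positions,
      residue = seqs[[k]][config$anchor_positions],
      ancestor_residue = anc[config$anchor_positions],
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, records)
  class(rec) <- c("protein_records", "data.frame")
  list(records = rec, truth = do.call(rbind, truth),
       anchor_truth = do.call(rbind, anchor_truth))
}

#' Simulate all configured families on one species tree
#'
#' Single entry point for the generator: samples the species tree, draws
#' the shared base ancestor, and evolves every configured family on the
#' same tree. All randomness flows from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `eif4e_sim` with `records`, `truth`,
#'   `anchor_truth`, `events` (duplication log), `tree`, `config`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- .sample_tree(config)
  base <- .random_core(config)
  recs <- list(); truths <- list(); anchors <- list(); events <- list()
  for (fam in config$families) {
    out <- .evolve_family(tree, config, fam, base)
    recs[[fam$name]] <- out$records
    truths[[fam$name]] <- out$truth
    anchors[[fam$name]] <- out$anchor_truth
    events[[fam$name]] <- data.frame(
      family = fam$name, event = "duplication_before_species_root",
      stem_divergence = config$family_divergence, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, recs)
  rownames(rec) <- NULL
  class(rec) <- c("protein_records", "data.frame")
  truth <- do.call(rbind, truths); rownames(truth) <- NULL
  anchor_truth <- do.call(rbind, anchors); rownames(anchor_truth) <- NULL
  ev <- do.call(rbind, events); rownames(ev) <- NULL
  structure(list(records = rec, truth = truth,
                 anchor_truth = anchor_truth, events = ev, tree = tree,
                 config = config),
            class = "eif4e_sim")
}

#' Write a simulation to disk
#'
#' Emits `sequences.fasta`, `truth_sequences.tsv`, `truth_anchors.tsv`,
#' `events.tsv` and `species_tree.nwk`. Re-running with the same
#' configuration reproduces the files byte for byte.
#'
#' @param sim A [simulate_families()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
emit <- function(sim, out_dir) {
  stopifnot(inherits(sim, "eif4e_sim"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("emit: cannot create directory ", out_dir, call. = FALSE)
  if (nrow(sim$records) != nrow(sim$truth))
    stop("emit: truth row count does not match record count",
         call. = FALSE)
  paths <- c(
    fasta = file.path(out_dir, "sequences.fasta"),
    truth = file.path(out_dir, "truth_sequences.tsv"),
    anchors = file.path(out_dir, "truth_anchors.tsv"),
    events = file.path(out_dir, "events.tsv"),
    tree = file.path(out_dir, "species_tree.nwk"))
  write_fasta(sim$records, paths[["fasta"]])
  write_report_tsv(sim$truth, paths[["truth"]])
  write_report_tsv(sim$anchor_truth, paths[["anchors"]])
  write_report_tsv(sim$events, paths[["events"]])
  to_newick(sim$tree, path = paths[["tree"]])
  invisible(paths)
}

#' Anchor catalog for a simulated data set
#'
#' Builds an `anchor_catalog` whose reference is the first simulated
#' sequence: the two class-diagnostic positions plus every simulated
#' anchor site (role `cap`), with the reference's own residues as the
#' expected states. Suitable for [classify_family()] and
#' [report_substitutions()] on alignments of the simulated records.
#'
#' @param sim A [simulate_families()] result.
#' @return An `anchor_catalog` data frame.
#' @export
synthetic_anchor_catalog <- function(sim) {
  ref <- sim$truth[1L, ]
  ref_chars <- .seq_chars(sim$records$sequence[1L])
  anc <- sim$anchor_truth[sim$anchor_truth$id == ref$id, ]
  cat_df <- rbind(
    data.frame(reference_id = ref$id, position = ref$diag1_pos,
               expected = ref_chars[ref$diag1_pos],
               role = "class_diagnostic", scheme = "family_local",
               stringsAsFactors = FALSE),
    data.frame(reference_id = ref$id, position = ref$diag2_pos,
               expected = ref_chars[ref$diag2_pos],
               role = "class_diagnostic", scheme = "family_local",
               stringsAsFactors = FALSE),
    data.frame(reference_id = ref$id, position = anc$position,
               expected = anc$residue, role = "cap",
               scheme = "family_local", stringsAsFactors = FALSE))
  as_anchor_catalog(cat_df)
}
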