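---
title: "Comparative analysis of insect eIF4E-family proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of insect eIF4E-family proteins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eif4efam)
```

## The biological problem

The eukaryotic translation initiation factor 4E (eIF4E) binds the
m^7^GpppN cap at the 5′ end of mRNAs and, with the scaffold eIF4G and the
helicase eIF4A, recruits mRNAs to the ribosome. The cap is stacked
between two conserved tryptophans (Trp-56 and Trp-102 in mouse numbering)
with a third (Trp-166) contacting the N7-methyl group; 4E-binding
proteins (4E-BPs) compete with eIF4G for an overlapping surface; and in
several metazoans eIF4E is regulated by phosphorylation of a C-terminal
serine (Ser-209 in mouse, Ser251 in *Drosophila melanogaster* eIF4E-1).
Insect genomes — uniquely, those of the genus *Drosophila* — carry
multiple *eIF4E* paralogs (eIF4E-1 through eIF4E-7) plus one copy of the
Class II relative *4E-HP*, while other insect genomes carry a single
Class I gene and a single *4E-HP*.

eIF4Es fall into three classes by the residues homologous to human eIF4E
Trp-43 and Trp-56:

* **Class I** — Trp at both positions;
* **Class II** — Tyr/Phe/Leu at the first and Tyr/Phe at the second;
* **Class III** — Trp at the first and Cys/Tyr at the second.

This package turns the comparative analysis of such a family — multiple
alignment, conservation profiling, functional-residue bookkeeping, class
assignment, phylogram construction, and inventory summarization — into a
tested, deterministic pipeline, together with a synthetic family
generator that provides ground truth for every stage.

## Pipeline model and procedure

### Progressive alignment (`msa`)

Pairwise alignment is global Needleman–Wunsch/Gotoh with affine gaps: a
gap run of length $k$ costs $g_o + (k-1)\,g_e$. Defaults are BLOSUM62
with $g_o = -10$, $g_e = -0.5$; the original study aligned with ClustalW
but did not publish its parameter set, so we pin standard protein
defaults and keep every value configurable. The traceback tie-break is
fixed (match/mismatch over gap-in-the-first-sequence over
gap-in-the-second), which makes output bit-identical across runs.

The guide tree is UPGMA over score-derived distances
$d_{ij} = 1 - s_{ij}/\min(s_{ii}, s_{jj})$ clamped to $[0,1]$, with ties
joined lowest-index first. UPGMA (rather than neighbor joining) is used
here because progressive alignment needs a rooted merge order; NJ is
reserved for the phylogram stage. Profiles are merged in guide-tree
order with profile–profile dynamic programming: the score for pairing
two profile columns is the average substitution score over all residue
pairs (pairs involving gaps contribute 0), with the same affine gap
penalties; averaging keeps the two-sequence case exactly equal to the
pairwise aligner. Once a gap column is introduced it is never removed.

The published alignments were additionally "improved by eye"; that step
is not reproducible and is deliberately not emulated — the deterministic
progressive alignment is the package's contract.

### Conservation profiling (`conservation`)

A column is **identical** when one residue occurs in at least 70% of all
rows, else **conservative** when one of the ten classical groups (STA,
NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW, GA) covers at least 70%,
else **unconserved**. Three conventions the legend of a figure cannot
settle are pinned here:

* the denominator is *all* rows — gaps and `X` count toward it but never
  support a residue or group (ambiguity must not create conservation);
* identical outranks conservative when both pass; group ties resolve by
  the canonical group order;
* for unconserved columns the reported fraction is the best coverage any
  residue or group achieved (winner `NA`).

### Anchors and cross-numbering (`anchors`)

Functionally important reference residues (cap, scaffold-binding,
phospho, class-diagnostic) are kept in a tabular catalog with an explicit
numbering-scheme tag, because the literature mixes mouse, human and fly
coordinates. Positions are mapped between proteins **only through
alignment columns, never by arithmetic offsets**. Observed states
partition into conserved / conservative substitution (shared group) /
nonconservative / deleted (gap) / undetermined (`X`). The packaged
default catalog contains only positions named in prose in the
comparative literature; figure-only annotations are not transcribed (we
do not guess at graphics), and users extend the catalog via the same TSV
format.

### Classification (`classify`)

`assign_class()` implements the three-class rule literally. One corner
case is worth stating: (Trp, Tyr) satisfies the Class III clause and
cannot satisfy Class II (Trp is not in {Tyr, Phe, Leu}), so it is
assigned III. Gap or `X` at either diagnostic position yields
`undetermined`; anything outside all rules is `unclassified`, never
silently forced. A `strict` flag drops sequences lacking the start
methionine before classification, mirroring the exclusion of partial
proteins. Inventory class labels can be cross-checked against
sequence-derived classes; mismatches are reported, not corrected.

### Distances and neighbor joining (`phylo`)

The default distance is the p-distance with pairwise deletion (sites
where either sequence has a gap or `X` are skipped per pair); the
Poisson correction $d = -\ln(1-p)$ and complete deletion are options.
The distance model behind the published phylograms was not stated, so a
pinned default matters more than a guess. Neighbor joining is the
classical algorithm (join the pair minimizing
$Q_{ij} = (n-2) d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}$), with Q-ties
broken by the lowest index pair, negative branch lengths clamped to zero
(raw values retained in an attribute for diagnosis), and the tree left
unrooted with a trifurcating final join. NJ is exact on additive
matrices, which the test suite exploits: path-length matrices of random
trees must be reproduced with Robinson–Foulds distance 0 and branch
lengths within $10^{-9}$. Newick output uses 6 decimal places and
underscores in place of label whitespace.

## The synthetic family generator

`sim_config()` / `simulate_families()` emulate the statistical structure
of the real data so every stage can be tested against known truth:

* a pure-birth species tree rescaled to unit depth (or a user-fixed
  Newick tree);
* paralog **families that diverge before the species root**: each family
  ancestor derives from a shared base sequence along a duplication stem,
  so family monophyly holds in truth;
* a conserved core (no indels) with planted class-diagnostic residues at
  core positions 43 and 56 and `n_anchor_sites` slowly evolving anchor
  sites; background sites substitute uniformly to another residue
  (Jukes–Cantor-like on 20 letters), anchors at
  `rate * anchor_rate_multiplier`;
* length-variable N-terminal extensions of random residues per tip
  lineage — the only indels, mirroring the ragged N-termini of real
  eIF4E paralogs while keeping the core alignment truth unambiguous.

Key defaults, chosen once as a realistic regime: `rate = 0.05`
substitutions/site over the unit-depth tree (orthologs ~95% identical,
congeneric scale); `core_length = 120`; `variable_nterm_max = 20`;
`n_anchor_sites = 10`; `anchor_rate_multiplier = 0.1`;
`family_divergence = 0.4` per stem. The stem value deserves its
rationale: two families differ by *twice* the stem divergence, and 0.4
per stem yields ~45–50% core identity between families — the similarity
scale of real eIF4E paralog families, and comfortably inside the
validity domain of alignment on uniform-model sequence. Much larger stem
values push cross-family identity toward the twilight zone where no
aligner can recover planted homology from a memoryless substitution
model; real proteins at such distances remain alignable only because of
structural constraints this simple model deliberately omits.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: rate heterogeneity beyond the
two-class anchor/background scheme, codon- or structure-aware
substitution preferences, indels inside the core, retroposition or
tandem-duplication genomic context, and alignment curation by eye.

## Numerical choices

* All tie-breaks (DP traceback, UPGMA joins, NJ Q-minimization, group
  order) are fixed, so the entire pipeline is a pure function of its
  inputs and seed.
* Floating-point tie detection in the DP traceback uses an absolute
  tolerance of $10^{-9}$; substitution scores are small rationals, so
  this is exact in practice.
* Guide-tree distances are clamped to $[0,1]$ before UPGMA (negative
  alignment scores can otherwise push the normalization above 1).
* Degenerate inputs fail loudly with names: ragged alignment rows,
  duplicate ids, illegal characters, anchor positions beyond the
  reference, pairs with zero comparable sites, Poisson at $p = 1$,
  asymmetric or non-finite distance matrices.
* Report TSVs have fixed, documented column orders; FASTA wraps at 60
  columns on write and accepts any wrap on read.

## Test-suite problem sizes

The suite validates against independent oracles at sizes chosen for a
thorough yet quick run: exhaustive alignment-path enumeration on all
sequence pairs up to length 2 over a 4-letter alphabet plus seeded
random pairs of lengths 3–6 under two gap regimes; exhaustive
conservation checks over every column of up to 4 rows on a 6-letter
alphabet plus sampled 5–6-row columns over the full 22-symbol alphabet;
the complete 22×22 diagnostic-pair table; 100 random 4–10-taxon additive
matrices for NJ exactness; and 20 end-to-end simulations at the default
generator conditions with frozen anchors, which must give 100% class
recovery and family monophyly. The packaged inventory reproduces the
published per-species gene counts (6/6/6/6, 5/5/5, 4/4/4, 3, and 7
*D. melanogaster* genes; 61 Class I members; 11 Class I orthologs
outside *Drosophila*; single-copy *4E-HP* throughout).

## Known limitations

* The progressive aligner has no iterative refinement or
  position-specific gap penalties; it will not reproduce ClustalW
  bit-for-bit, and on real twilight-zone paralogs a curated alignment
  will beat it.
* The default anchor catalog is deliberately minimal (prose-named
  positions only); serious use on a new family should ship its own
  catalog rows.
* Bootstrap support, maximum likelihood, and tree graphics are out of
  scope; the Newick output is meant for downstream tooling (`ape`,
  iTOL, FigTree).
* Class III calling is implemented as a rule, but genuinely partial
  Class III sequences (missing start methionine) are excluded rather
  than rescued, matching the source analysis.

## A worked micro-example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, anchor_rate_multiplier = 0)
sim <- simulate_families(cfg)
aln <- progressive_align(sim$records)
classify_family(aln, synthetic_anchor_catalog(sim))
summarize_inventory(load_inventory())
```

The README shows this session with its actual printed output; the
`scripts/acceptance.R` entry point re-derives every headline quantity
from scratch.
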