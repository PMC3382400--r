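Package: eif4efam
Title: Comparative Analysis of Insect eIF4E-Family Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative analysis of the insect
    eIF4E cap-binding protein family: progressive multiple sequence
    alignment with an affine-gap pairwise aligner and UPGMA guide tree,
    per-column conservation profiling at a 70% threshold using the ten
    classical conservative-substitution groups, mapping of functionally
    important reference residues (cap-binding, eIF4G/4E-BP-binding,
    phosphorylation, class-diagnostic) through alignments into orthologs,
    Class I/II/III assignment from the residues homologous to human eIF4E
    Trp-43 and Trp-56, neighbor-joining phylograms with Newick output, a
    transcription of the published gene inventory for the twelve Drosophila
    genomes and other insects, and a synthetic ortholog-family generator
    with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
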