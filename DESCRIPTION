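Package: opsinpipe
Title: Bait-Anchored Filtering, Rogue Pruning and Retinal-Binding-Site
    Profiling for Large Protein Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational stages for large-scale opsin (and general GPCR)
    phylogenies: exact-duplicate removal, bait-anchored extraction of a target
    clade from mixed sequence sets, iterative rogue-taxon and long-branch
    pruning driven by bootstrap consensus stability, gap-column trimming with
    column provenance, mapping of the retinal-binding lysine K296 (Ballesteros-
    Weinstein 7.43) of bovine rhodopsin through trimmed alignments, per-clade
    residue composition, NPxxY (7.53) motif calling and sequence-logo matrices,
    genus-based taxonomy annotation, and a deterministic synthetic sequence-
    family generator that plants lysine-loss clades, rogues, long branches,
    fragments and decoys so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    phytools,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
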