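Package: genefamsim
Title: Hierarchical Simulation of Gene Family Evolution in Species Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates multi-gene-family evolution under a hierarchical
    three-tree model: gene trees evolve by a (bounded) multispecies
    coalescent inside locus trees, which evolve by duplication, loss,
    replacing horizontal gene transfer and gene conversion inside a
    birth-death species tree.  Parameters can be fixed or sampled from
    prior distributions per replicate and per gene family, and three
    independent layers of mean-one Gamma rate multipliers (species-,
    family- and gene-by-lineage-specific uncorrelated relaxed clocks)
    convert genealogies from generations to expected substitutions per
    site.  Includes exact sampling of coalescent-bounded subtrees via a
    lineage-count dynamic program with inverse-transform sampling, Newick
    and Nexus tree input/output, and tools to quantify the systematic
    overestimation of duplication times by reconciliation methods that
    ignore locus trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
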