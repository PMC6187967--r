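Package: nodevol
Title: Comparative Expression and Molecular Evolution of Root Nodule Symbiosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of the evolution of root nodule
    symbiosis (RNS) across host lineages. Merges per-gene ortholog predictions
    into mutually exclusive ortholog groups, classifies genes and groups as
    nodule- or root-enhanced per species, quantifies cross-species expression
    concordance with Pearson correlations and a permutation-tested dissonance
    statistic, and tests branch-specific shifts in selection pressure with a
    Goldman-Yang codon substitution model (per-branch-class dN/dS, Felsenstein
    pruning likelihood, Kishino-Hasegawa and Shimodaira-Hasegawa RELL tests
    over four evolutionary scenarios). Includes simulators for ortholog
    predictions, paired cross-species fold changes, and codon alignments so
    every stage of the pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
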