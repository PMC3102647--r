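Package: chromfold
Title: Polymer Models of Hierarchical Chromatin and Genome Folding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic and simulation tools for studying the hierarchical
    organization of eukaryotic genomes with polymer theory. Implements
    worm-like-chain (WLC) compaction of gene loci under persistence-length
    changes and the associated Flory interaction amplification, the
    freely-jointed-chain folding-index framework linking persistence length
    to genome-wide compaction, lattice Monte Carlo simulation of phantom
    semiflexible chains with flexible hinges, the deterministic two-angle
    geometry of nucleosome fibers, and Gaussian-chain loop models (random
    loop, random-walk/giant-loop) with scaling-exponent and moment-ratio
    diagnostics. Includes conformation writers (XYZ/PDB), TSV result tables
    with metadata sidecars, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
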