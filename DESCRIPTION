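Package: sbsfold
Title: Strings-and-Binders Polymer Modelling of Chromatin Folding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the Strings-and-Binders Switch (SBS) polymer model of
    chromatin: Langevin dynamics of a self-avoiding bead chain folded by
    diffusing binder particles, thermodynamic phase classification
    (coil, disordered globule, ordered globule), decomposition of contact
    probability decay P(s) as a mixture of pure folding states, simulated
    annealing inference of multi-type binding-site profiles from Hi-C style
    contact matrices, 3D reconstruction of the inferred loci, and correlation
    of inferred binding domains with epigenomic signal tracks. Includes
    generators for synthetic loci with planted binding-domain architectures
    so the whole pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    pracma,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
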