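Package: rxnvec
Title: Reaction-Vector-Based De Novo Molecular Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives reaction difference vectors from known reactions encoded as
    atom-pair (AP2/AP3) descriptor changes, applies them to new reactants to
    enumerate synthetically precedented products, and runs an "inside-out"
    multi-objective design loop: reference ligands are fragmented
    retrosynthetically, fragments are replaced by similar building blocks
    (count FeatMorgan fingerprints, Euclidean distance), and products are
    reassembled forward under scoring and a passive filter cascade
    (reactive-group conversion, substructure and Lipinski filters). Also ships
    Morgan-fingerprint Tanimoto similarity, stereoisomer enumeration, and PAMPA
    apparent-permeability and membrane-retention calculators. Molecular
    primitives are computed with RDKit through a bundled Python worker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with RDKit available as 'python' on PATH
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
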