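Package: ecfpPool
Title: Substructure Pooling for Extended-Connectivity Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for turning molecules into fixed-length binary
    extended-connectivity fingerprints (ECFP/FCFP) via substructure
    pooling. Implements circular-substructure enumeration with standard or
    pharmacophoric atomic invariants, and four pooling operators that map
    a compound's set of 32-bit substructure identifiers to an L-bit
    vector: classical hash-based folding, frequency-based Sort & Slice,
    chi-squared filtering, and mutual-information maximisation. Includes
    SMILES standardisation and desalting, information-theoretic
    diagnostics of substructure-frequency distributions, a synthetic
    molecule-library generator with planted substructure signal, and a
    scaled-down cross-validated benchmarking harness (random, stratified
    and Bemis-Murcko scaffold splits; random-forest models; MAE, AUROC
    and AUPRC metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    ranger,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
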