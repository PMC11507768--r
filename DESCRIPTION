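Package: jple
Title: Joint Protein-Ligand Embedding for RNA-Binding Specificity Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the RNA-binding specificities of RRM- and
    KH-domain RNA-binding proteins from amino-acid sequence with the
    Joint Protein-Ligand Embedding (JPLE) model, a linear auto-encoder
    whose principal axes are selected by their contribution to the
    variance of the RNA-specificity block. Includes gapped peptide
    k-mer featurization of RNA-binding regions, quantification of
    RNAcompete-style probe arrays into 7-mer Z-score profiles,
    protein and RNA queries with global and kernel-weighted local
    decoding, residue importance scores for mapping
    specificity-determining residues, motif utilities (specifically
    bound 7-mer calls, position frequency and affinity matrices,
    binding-score scanning), pairwise domain-aware amino-acid
    sequence identity with a homology-transfer baseline, and a
    synthetic benchmark generator with planted peptide-to-RNA
    specificity structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Biostrings,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
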