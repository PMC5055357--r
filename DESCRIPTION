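Package: dualOCCF
Title: Dual-Regularized One-Class Collaborative Filtering for
    Chemical-Protein Interaction Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide prediction of chemical-protein (off-target)
    interactions by weighted one-class matrix factorization with
    graph-Laplacian regularization on chemical-chemical (Tanimoto/ECFP)
    and protein-protein (BLAST bit-score) similarity networks. Includes
    readers for interaction, fingerprint and BLAST tabular inputs,
    IC50-based activity labeling, histogram-based score calibration
    against active/inactive/ambiguous pairs, a stratified
    cross-validation benchmark reporting true-positive rate at top
    percentile cutoff ranks, Markov clustering of latent drug profiles
    for repurposing analysis, and a block-model synthetic data
    generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
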