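Package: tcrhla
Title: Peptide-Agnostic TCR-HLA Binding Prediction from T Cell Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts binding between T cell receptor (TCR) beta chains and
    Class I HLA alleles without using peptide information. Provides a naive
    Bayes model linking V-beta gene usage to HLA alleles, a neural binding
    predictor built on a CDR3 sequence autoencoder with learned gene and
    allele embeddings, a two-stage training scheme for bulk repertoires in
    which each TCR carries several candidate host alleles, a CD4/CD8
    compartment classifier for unsorted repertoires, and evaluation tools
    including group accuracy, scrambled-label null curves, the ambiguity
    ceiling on ROC AUC, and donor co-occurrence cross-validation. Synthetic
    repertoire generators with planted gene-allele associations and sequence
    motifs support end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
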