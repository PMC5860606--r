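Package: deepgo
Title: Ontology-Aware Deep Learning for Protein Function Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) annotations of proteins from amino-acid
    sequence and protein-network embeddings. Sequences are encoded as overlapping
    amino-acid trigrams and fed to a learned-embedding 1D convolutional feature
    extractor; the resulting features, optionally fused with 256-dimensional
    network embeddings, are classified by a hierarchy of per-class sigmoid layers
    wired after the GO subclass structure, with recursive max-merge layers that
    guarantee ancestor scores dominate descendant scores. Includes OBO parsing,
    true-path-rule annotation propagation, term selection, a BLAST-style best-hit
    annotation-transfer baseline, a sequence-identity train/test split, CAFA-style
    protein-centric and term-centric evaluation metrics, and a synthetic-fixture
    generator (toy ontologies, motif-planted sequences, class-correlated
    embeddings) so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
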