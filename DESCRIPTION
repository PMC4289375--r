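Package: mirtargo
Title: Integration of miRNA-Target Evidence and Gene Ontology
    Over-Representation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates experimentally validated and computationally
    predicted miRNA-gene interaction sets, filters prediction scores with a
    two-component Gaussian posterior-probability model, runs Gene Ontology
    over-representation analysis (one-sided Fisher exact test with
    Bonferroni family-wise error control) on the resulting gene set under
    true-path annotation propagation, condenses the significant-term DAG
    into a concise set of functional areas, and provides the random-gene-set
    null control and miRNA degree-split robustness checks. A synthetic-data
    module generates ontologies, annotation corpora, interaction tables and
    prediction scores with known ground truth so every stage is testable
    offline.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
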