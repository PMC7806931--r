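Package: phenoplex
Title: Multiplex Gene-Phenotype Network Analysis of Comorbid Disease Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses two-layer (multiplex) networks over a shared
    set of disease-associated genes: a protein-protein interaction layer
    thresholded on interaction confidence, and a phenotype-similarity layer in
    which genes are linked when the cosine similarity of their
    skewness-weighted phenotype-association vectors exceeds a per-pair
    permutation threshold. Modules are detected by maximising a weighted
    two-layer modularity with a restarted Louvain heuristic, layers are
    compared against degree-preserving null ensembles, modules are
    characterised by hypergeometric and empirical-score enrichment with
    Benjamini-Hochberg correction, and candidate genes are prioritised via
    cross-network module overlap and centrality. Includes a synthetic-data
    generator with planted module structure so the full pipeline is testable
    without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
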