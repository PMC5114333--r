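Package: qatopics
Title: Topic Hierarchies and Hierarchy-Routed Retrieval for Health
    Question-Answering Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Organizes an unstructured corpus of community health
    question-answering (QA) records into a profiled topic hierarchy: a
    prior-knowledge first layer routed by per-category margin classifiers,
    breadth-first node expansion with latent Dirichlet allocation whose child
    count is selected by held-out perplexity, a shrinkage test on inter- vs
    intra-node similarity that decides when a node is specific enough to stop,
    multi-leaf record assignment by the leading-gap heuristic, and node
    labeling with standard terminologies by noun-phrase extraction and voting
    normalization. On top of the hierarchy it provides a retrieval engine that
    routes queries to leaves and reranks candidates by a graph random walk
    over fused lexical, syntactic and topical similarity kernels, plus the
    matching evaluation metrics (parent-child tuple accuracy, taxonomy
    cohesiveness, S@K/P@K, NDCG@n) and a synthetic-corpus generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
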