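Package: PathQuery
Title: Path-Feature Indexing and Locality-Guided Subgraph Isomorphism Search
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Filter-and-verify subgraph isomorphism search for databases of
    node-labeled undirected graphs and for single large graphs (chemical
    compounds, protein-protein interaction and transcription networks).
    Every simple label path of bounded length is indexed together with its
    occurrence count and the set of vertices it starts from, stored as bit
    arrays. Queries are answered by occurrence-count pruning, a second
    locality-based pruning step that intersects per-vertex start sets, and a
    VF2-style backtracking matcher whose per-vertex candidate sets are the
    surviving compatibility bitsets. Includes seeded generators for
    scale-free and molecule-like benchmark graphs, breadth-first query
    sampling, and an independent brute-force matching oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, jsonlite, withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
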