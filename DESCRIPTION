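Package: ikap
Title: Identifying Major Cell Population Groups in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic selection of clustering parameters for single-cell
    RNA-sequencing. For a range of top principal components (nPC), cells are
    clustered at high resolution on a shared-nearest-neighbor graph, nested
    coarser partitions are produced by iterative nearest-centroid merging, and
    each partition is scored with a gap statistic against a uniform reference.
    Candidate (nPC, k) group sets are picked from the gap-increase matrix by a
    greedy rule, ranked by a decision-tree classification error built from
    one-vs-rest differentially expressed genes, and the best set of major cell
    groups is reported. Recursive application inside groups builds a
    multi-layer cell ontology. Includes a negative-binomial hierarchical
    simulator with planted marker genes for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    rpart,
    jsonlite,
    methods,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
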