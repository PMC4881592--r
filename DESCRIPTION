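Package: mirphylomark
Title: High-Confidence miRNA Cancer Biomarker Selection by Intersecting
    Target-Pattern Groups with a Stem-Loop Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects high-confidence microRNA cancer biomarkers by combining
    two independent clusterings of the same miRNA panel: a grouping of miRNAs
    by identical binary cancer-target vectors (with a UPGMA dendrogram over
    Euclidean distances between the vectors), and a single-linkage phylogeny
    of miRNA stem-loop sequences under the Jukes-Cantor substitution model.
    Maximal phylogenetic clades falling entirely inside one target group are
    reported as biomarker sets, and selections are scored against an
    experiment-supported miRNA-disease validation table with per-cancer
    sensitivity and specificity. Includes simulators for sequence families
    and binary association matrices, packaged reference tables, and a
    reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
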