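Package: ffadj
Title: Family-Free Gene Order Comparison by Weighted Adjacency Matchings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pairwise comparison of gene orders without prior gene family
    assignment. Two genomes are connected by a weighted bipartite graph whose
    edge weights are normalized gene-gene similarities (e.g. relative
    reciprocal BLAST scores), and a matching is sought that maximizes a convex
    combination of weighted conserved adjacencies and weighted matched edges.
    Provides an exact solver based on a 0-1 linear program solved by
    branch-and-bound, a greedy maximum-common-substring heuristic, a
    breakpoint-like distance derived from the optimal matching, neighbor
    joining tree reconstruction with Robinson-Foulds evaluation, and a seeded
    simulator of gene orders evolving by inversions, duplications and losses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
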