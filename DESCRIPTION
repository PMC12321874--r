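Package: specfp
Title: Spectral Fingerprinting and Comparison of Pathway Network Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares labeled collections of biological pathway networks by
    the spectra of their adjacency matrices. Builds genes-only, undirected,
    unweighted pathway graphs from KEGG KGML files, edge lists or GraphML;
    tests whether two (or more) sets of graphs arise from the same random
    generating process via permutation tests on the Jensen-Shannon divergence
    between mean spectral densities; hierarchically clusters pooled graph
    collections by spectral distance with degree, betweenness and closeness
    connectivity baselines scored by the adjusted Rand index; and prioritizes
    genes by a Kullback-Leibler degree-profile distinctiveness score whose
    top-ranked ("driving") genes induce a Jaccard-similarity fingerprint over
    pathways. Includes seeded synthetic generators for random-graph sets,
    planted two-cluster pathway collections, and miniature KGML documents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    xml2,
    jsonlite,
    mclust,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
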