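Package: combiclust
Title: Combinatorial Descriptor-Subset Selection for Patient Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Exhaustive small-subset descriptor selection for k-means-style
    clustering of clinical tables. Every combination of two or three numeric
    descriptors is clustered (agglomerative centroid linkage by default) on
    its complete cases, scored by the global within-cluster variance, and
    ranked; undersized clusters are rejected as invalid. Includes a
    standardized cluster-separation statistic for descriptor profiles, a
    confirmatory Ward-linkage hierarchical clustering with a Sneath-style
    significance cut, and a planted-cluster simulation benchmark that
    estimates the probability of recovering the signal descriptors as a
    function of cluster separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
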