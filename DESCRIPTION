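Package: dcornet
Title: Differential Correlation Networks for Designed Metabolomics Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Second-moment analysis of wide metabolite-quantification tables
    from designed experiments. Computes per-subset pairwise Pearson
    correlations, tests each metabolite pair for a change in correlation
    between two contrasting sample subsets via the Fisher r-to-z two-sample
    test, assembles signed differential-correlation networks with
    Cytoscape-ready edge attributes (CSV and GraphML), and scores every
    pair's cross-partition stability as the standard deviation of its
    z-transformed correlations. Includes a synthetic-data generator that
    emulates a multi-genotype, multi-mulch tomato field design with planted
    between-subset correlation differences, so every stage can be verified
    against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
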