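Package: cernaTriad
Title: Multi-Layer RNA Differential Expression and ceRNA Triad Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-quantification analysis of multi-group, multi-layer
    (mRNA, miRNA, lncRNA) expression experiments in a renal-fibrosis
    treatment setting: fold-change plus t-test differential expression
    calling, Fisher's-exact pathway over-representation, Pearson-power
    coexpression networks, target-map-constrained miRNA edges, and
    lncRNA-miRNA-mRNA competing-endogenous-RNA (ceRNA) triad inference.
    Also implements semiquantitative histopathology scores (glomerular
    sclerosis index, tubulointerstitial injury index), 2^-ddCt relative
    qPCR quantification, and a negative-binomial multi-omic simulator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'differential.R'
    'enrichment.R'
    'networks.R'
    'scoring.R'
    'simulate.R'
    'pipeline.R'
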