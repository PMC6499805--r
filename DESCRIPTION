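Package: pvrnet
Title: Transcriptome and Network Analysis Pipeline for Proliferative
    Vitreoretinopathy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of the transcriptome analysis
    used to implicate the p38-MAPK interaction network in proliferative
    vitreoretinopathy (PVR): dual-method differential expression with a
    fold-change intersection rule, singular-value-decomposition eigengene
    analysis with polar eigenspace coordinates, seed-gene network-neighborhood
    enrichment with a resampling null and a binomial-proportion Bayes factor,
    sub-network betweenness and community analysis, and an inter- versus
    intra-line coefficient-of-variation decomposition of membrane counts.
    Includes a synthetic-data module that emulates the three-group design
    (control RPE, TNT-treated RPE, PVR membranes) with negative-binomial
    counts, planted fold-changes, an RPE-admixture structure for PVR, and a
    scale-free interaction network with planted neighborhood enrichment, so
    the whole pipeline is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
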