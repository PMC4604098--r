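Package: FePiOverlap
Title: Cross-Stress Analysis of Iron-Deficiency and Phosphate-Starvation
    Transcriptomes in Arabidopsis Roots
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integration analysis of genes responding to both iron
    deficiency and phosphate starvation in Arabidopsis roots. Implements
    replicate-wise fold-change computation with an undetermined-control
    convention, overlap and fold-cutoff filtering of differentially
    expressed gene lists, a four-way classification of regulatory
    patterns across the two stresses, hierarchical clustering of log2
    fold-change profiles, Pearson-threshold co-expression networks with
    connected-component module detection, gene ontology
    over-representation analysis with the elim decorrelation algorithm,
    and degenerate IUPAC motif scanning of upstream promoter sequences
    for the PHR1-binding P1BS element (GNATATNC). Ships synthetic-data
    generators with known ground truth for every input class so the full
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    jsonlite,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, Network, GO, MotifDiscovery
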