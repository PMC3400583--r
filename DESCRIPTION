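Package: mirtfnet
Title: miRNA-TF Mediated Regulatory Network Construction from Feed-Forward Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs combined microRNA-transcription factor (miRNA-TF)
    regulatory networks from five classes of regulatory edges (TF-gene,
    TF-miRNA, miRNA-gene, miRNA-TF and gene-gene coexpression). Enumerates
    and classifies 3-node and 4-node feed-forward loops (TF-FFL, miRNA-FFL,
    composite-FFL), retains statistically significant miRNA-TF co-targeting
    pairs via a cumulative hypergeometric test with FDR control, merges
    loops sharing a TF-miRNA regulation into a network, and provides
    topology analyses (degree summaries, hubs, composite and seeded
    subnetworks, TF-miRNA feedback loops, k-clique-percolation communities,
    node ablation). Helper stages cover TargetScan-style target filtering,
    Match-style position-weight-matrix promoter scanning with cross-species
    conservation, mutual-information coexpression inference with
    data-processing-inequality pruning, permutation, Kolmogorov-Smirnov and
    Fisher enrichment statistics, and seeded synthetic-data generators with
    known ground truth for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
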