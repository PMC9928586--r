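Package: lungSpatial
Title: Cluster-Graph Trajectories, Panel Design and Airway Zonation for
    Developing-Lung Spatial Transcriptomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational analyses used in spatial atlases of
    the developing human lung: cluster-level graph abstraction of
    shared-nearest-neighbour cell graphs with inverse-probability shortest
    paths between immature and mature states; simulation-driven selection of
    targeted in-situ gene panels with a negative-binomial probabilistic cell
    typer; spot-level cell-type co-localization neighbourhood graphs from
    deconvolution fractions; two-axis (radial and proximal-distal) airway
    zonation scoring of binned molecule reads and Visium-like spots; and
    hexagonal binning of decoded molecule coordinates with epithelial and
    neuroendocrine count filters and Leiden clustering. Every pipeline input
    can be generated synthetically with planted ground truth, so all stages
    are testable without access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Transcriptomics, SingleCell, Spatial, GraphAndNetwork
RoxygenNote: 7.3.3
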