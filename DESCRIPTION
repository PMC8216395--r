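Package: thyromorph
Title: Vertex-Model Simulation of Embryonic Thyroid Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional vertex model of the developing thyroid lobe:
    differential proliferation of central and peripheral epithelial cells,
    VEGF-driven recruitment and invasion of endothelial tip and stalk cells,
    fission of the epithelial mass into islets under endothelial boundary
    conditions, and apico-basal polarisation of epithelial cells leading to
    follicular lumen formation. Includes a Voronoi-based initial-condition
    builder that turns segmented cell-centre tables (or a synthetic
    E13.5-like generator) into simulable tissue meshes, a forward-Euler
    integrator with T1/T2/T3 junctional rearrangements, rosette resolution
    and shortest-axis cell division, a reaction-diffusion morphogen solver
    on the cell-adjacency graph, and summary statistics (endothelial area
    fraction, islet count, lumen counts, proliferating fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    generics,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
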