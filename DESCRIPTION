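Package: vesselquant
Title: 3D Quantification of Tight-Junction Density and Perivascular
    Cellularity in CNS Microvessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of inflamed central-nervous-system
    microvessels from multichannel confocal z-stacks. Builds closed 3D
    surfaces for the endothelial and parenchymal basement membranes by
    lofting per-slice vessel contours, measures microvascular surface
    area, computes claudin-5 tight-junction staining density (total
    intensity per unit surface area), detects DRAQ5-stained nuclei as
    spot objects with a physical size filter, classifies them into
    luminal, perivascular and parenchymal compartments, and summarises
    their 3D spread. Includes clinical-course analytics for experimental
    autoimmune encephalomyelitis (incidence, mean day of onset, mean
    maximum score, disease index, ascending slope and the associated
    group tests), CFSE dilution proliferation indices, and a synthetic
    vessel-phantom generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
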