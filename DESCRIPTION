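Package: cortexmesh
Title: Membrane-Protein Subdiffusion and Cortical-Actin Meshwork Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying anomalous diffusion of membrane proteins and
    quantifying the cortical actin meshwork that obstructs them. Simulates the
    reference random-walk classes used to discriminate subdiffusion mechanisms
    (exact fractional Brownian motion via circulant embedding, blind-ant walks
    on obstructed site-percolation lattices, and hop diffusion across permeable
    fences); computes time-averaged mean square displacements, anomalous-exponent
    fits, and lag-resolved turning-angle distributions; synthesises actin-like
    meshworks with log-normal compartment statistics together with
    finite-precision single-molecule localizations; and analyses superresolution
    reconstructions by sliding-window rendering, Euclidean distance maps,
    watershed compartment morphometry, perimeter-area scaling, and box-counting
    fractal dimension.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
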