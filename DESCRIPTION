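Package: surfseg
Title: Surfel-Based 3D Image Segmentation with Self-Adapting Oriented Particle Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments objects in 3D intensity volumes with a coarse-grained
    membrane simulation: a cloud of oriented particles (surfels) inflates or
    deflates under a user-set pressure, attaches to local image maxima along
    each particle normal, and adapts its particle number to the local surface
    density, so that topology changes (fusion, fission) arise naturally from
    the interaction rules. Provides seed construction (spheres, planar-ROI
    skeletons, imported clouds), synthetic benchmark phantoms, oriented
    point-cloud export in ASCII PLY, and shape measurements (volume, surface
    area, centre of mass) from the converged cloud.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
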