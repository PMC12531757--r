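Package: cardiochip
Title: Quantification of Calcium Transients, Microvascular Morphology and
    Permeability in Vascularized Heart-on-a-Chip Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-quantification pipeline for vascularized cardiac
    microphysiological systems: GCaMP calcium-transient beat detection and
    kinetic parameterization with coefficient-of-variation arrhythmia
    indices, microvascular network morphometry (triangle thresholding,
    skeletonization, junction/endpoint/length statistics), apparent
    vascular permeability estimation from tracer time-lapse imaging, and
    liposome extravasation colocalization. Every analysis is paired with a
    seeded synthetic-data generator carrying ground-truth records, so the
    full pipeline is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    multcomp,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
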