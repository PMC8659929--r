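Package: rnflseg
Title: Retinal Nerve Fiber Layer Segmentation in Peripapillary OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of the retinal nerve fiber layer (RNFL) in
    2D peripapillary B-scan optical coherence tomography images. Grayscale
    mathematical morphology (openings, closings, reconstruction by geodesic
    dilation) provides a robust coarse localisation of the layer boundaries;
    a frequency-domain B-spline active contour refines each boundary to
    subpixel precision; a blood-vessel shadow mask cancels external forces in
    shaded columns. The package reports RNFL thickness per TSNIT sector and
    ships a synthetic phantom generator with known ground-truth boundaries so
    the whole pipeline can be validated without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
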