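Package: bioinklab
Title: Quantitative Characterization of Shape-Shifting Bioinks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterize alginate-based, internally crosslinked
    bioinks for extrusion-based bioprinting: gel-point and yield-point
    detection from oscillatory rheometry sweeps, shear-thinning power-law
    fits, three-interval thixotropic recovery, spherical-cap drop-spreading
    geometry (spreading ratio and minimum layer height), shape-fidelity
    printability scores (spreading factor, uniformity, perimeter, pore and
    printability coefficients), a capillary wall-stress extrusion-pressure
    model, and image-based measurement of drops, fibers, grids, powder
    particles and embedded-cell area fractions. Seeded synthetic-data
    generators emulate every instrument input with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
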