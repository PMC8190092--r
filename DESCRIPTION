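Package: thylaquant
Title: Quantitative Analysis of Thylakoid Membrane Biogenesis in Rod-Shaped Cyanobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the spatial organisation of photosynthetic
    complexes and thylakoid membranes in rod-shaped cyanobacteria such as
    Synechococcus elongatus. Implements cell-periphery fluorescence profiling
    along an anchored spherocylinder outline (patchiness, longitudinal-side
    asymmetry, colocalization), thylakoid layer counting and inter-layer
    spacing from thin-section-like electron micrographs with subpixel peak
    refinement, polynomial protein-abundance trajectory fitting with adjusted
    R-squared, and chlorophyll photometry. A forward simulator generates
    two-channel fluorescence and TEM-like images of spherocylindrical cells
    with full ground truth (concentric thylakoid shells, clustered or
    asymmetric protein point distributions, PSF blur, Poisson and Gaussian
    noise) so every analysis step can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    grDevices,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
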