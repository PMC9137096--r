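Package: OrganoidStack
Title: Z-Stack Focus Stacking and Live/Dead Quantification for 3D Organoid Imaging Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale development and validation of high-throughput
    organoid imaging assays in deep 3D gel cultures. Provides a synthetic
    microscopy simulator (spherical organoids/microspheres in a ~1 mm Matrigel
    dome, depth-of-field and defocus blur, Calcein-AM/PI live-dead staining
    kinetics, gel autofluorescence background with Cu2+ quenching, drug
    treatment effects), z-stack acquisition planning with closed-form and
    Monte-Carlo capture-efficiency estimates, extended-depth-of-field (EDF)
    fusion of z-stacks via a variance-of-Laplacian focus measure,
    threshold/watershed segmentation with per-object area, minimum-Feret
    short-diameter and channel-intensity measurements, and assay analytics:
    labeling rate, overlap rate, survival rate as percent of day 0, size-change
    chemosensitivity calls against a configurable cutoff, and
    control-vs-treated group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
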