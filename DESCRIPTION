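Package: vesselseg
Title: Two-Phase Level Set Segmentation of Retinal Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segments blood vessels in retinal fundus images with a Bayesian
    region model that couples each pixel's likelihood to its spatial
    neighborhood, minimized by a two-phase level set evolution with a
    contour-length penalty and a distance-regularization term that keeps the
    level set function well conditioned without reinitialization. Includes
    DRIVE/STARE-style image loading with field-of-view (FOV) mask estimation,
    FOV-restricted accuracy/sensitivity/specificity scoring, a seedable
    vessel-phantom generator for ground-truthed testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    EBImage,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Segmentation, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
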