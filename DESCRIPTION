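Package: overlayAug
Title: Artifact Overlay Augmentation for Slide Preview Tissue Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Copy-paste overlay augmentation for whole-slide-scanner preview
    images. Extracts labeled slide artifacts (felt-pen markings, air bubbles,
    dirt speckles, brand marks) into a reusable bank, transforms them with
    seven seeded random operators (scaling, rotation, mirroring, HSV hue
    replacement, scratch attenuation, Perlin-noise fading, intensity scaling)
    and composites them onto clean previews with a masked subtractive blend,
    producing augmented image/mask training pairs together with the binary
    segmentation metrics (sensitivity, precision, F1, IoU) used to validate
    tissue-detection models. Includes a synthetic fixture generator so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Preprocessing, Segmentation, Visualization
RoxygenNote: 7.3.3
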