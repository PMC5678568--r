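Package: stomataMorph
Title: Automated Stomata Detection and Pore Morphometry for Leaf Micrographs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: A fully automated pipeline for locating stomata in light-microscope
        images of leaf epidermal imprints and measuring their pore morphology.
        Detection uses a trainable attentional cascade of boosted decision
        stumps over histogram-of-oriented-gradients (HOG) features with
        sliding-window scanning and non-maximum suppression. Pore morphometry
        runs a two-path engine: binary segmentation for stomata with complete
        pore boundaries, and skeletonization with direct least-squares ellipse
        fitting for stomata whose boundaries are only partially visible.
        Includes object-detection evaluation metrics, a seeded synthetic
        epidermis micrograph generator with per-stoma ground truth, and a
        command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, EBImage, Rcpp, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Classification
RoxygenNote: 7.3.3
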