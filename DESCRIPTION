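Package: gmstage
Title: Gray-Matter Segmentation and Staging of Brain MRI Slices with
    Phantom Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-phase analysis of 2D axial brain slices for staging
    Alzheimer's disease on synthetic brain phantoms: whole-brain
    segmentation with a vanilla U-Net, gray-matter segmentation with a
    multi-layer U-Net trained under class-balanced cross-entropy or Dice
    loss, hybrid classification combining a multi-scale convolutional
    feature head with a grid-searched kernel support vector machine over
    the classes AD / MCI / CN, and gradient saliency maps with
    quadrant-level quantification. Includes a deterministic phantom
    generator with exact ground-truth masks, the full segmentation and
    classification metric battery, one-vs-rest ROC analysis and the
    McNemar paired test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    EBImage,
    jsonlite,
    png,
    RNifti,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
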