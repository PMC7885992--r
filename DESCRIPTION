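Package: octcalc
Title: Two-Step Detection, Segmentation and Quantification of Coronary
    Calcified Plaque in Polar-Domain Intravascular OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for coronary calcified plaque analysis in
    polar-domain intravascular optical coherence tomography (IVOCT)
    pullbacks. A 3D convolutional network first classifies each frame of a
    pullback as containing major calcification or not; 1-D morphological
    opening/closing cleans the frame-label sequence into lesion intervals; a
    SegNet-style encoder-decoder with pooling-index unpooling then segments
    calcified pixels within those intervals, trained with weighted
    cross-entropy, Dice or Tversky losses and inverse-median-frequency class
    weights; a fully connected conditional random field with a Gaussian
    smoothness kernel refines the per-pixel probabilities by mean-field
    inference; missing frames inside lesions are filled by signed-distance
    shape interpolation; and clinically relevant calcium attributes (maximum
    arc angle, mean thickness, mean depth, lesion length, 0-4 calcium score)
    are quantified per lesion. A seeded synthetic polar-phantom generator
    provides training and evaluation data with pixel-level ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
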