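Package: morfse
Title: Mixture of Radiological-Finding-Specific Experts for Mammographic
    Patch Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a mixture-of-experts classifier for mammographic
    patches in which a gate network weighs two lesion-type-specific expert
    networks (a calcification expert and a mass expert), together with
    equal-weight and single-network baselines, training-data routing rules,
    patient-grouped repeated stratified k-fold out-of-fold evaluation, and
    from-scratch ROC statistics (midrank AUC, DeLong variance and paired
    test for correlated ROC curves).  A synthetic lesion-phantom generator
    produces labeled calcification, mass and normal-tissue patches with
    tunable finding-specific malignancy cues so the whole pipeline is
    exercisable at desk scale; loaders for mammography-style source data
    (monochrome DICOM or PNG plus segmentation masks and an annotation
    table) apply the patch-construction rules: lesion-centered crops,
    distortion exclusion, focal-asymmetric-density relabeling as mass, and
    binarization-based sampling of normal patches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
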