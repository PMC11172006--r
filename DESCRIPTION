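Package: taaft
Title: Threshold-Aware Accumulative Fine-Tuning for Lung Ultrasound Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for squeezing maximum value out of a limited external
    lung-ultrasound (LUS) dataset when adapting a single-center lung-sliding
    classifier to new institutions. Implements threshold-aware accumulative
    fine-tuning (TAAFT): patient-wise 2k-fold splitting, an accumulative
    fine-tuning schedule evaluated against dual fixed-size and variable-sized
    validation sets, class-imbalance upsampling from a sequestered pool of
    candidate M-mode images, and selection of the smallest training proportion
    meeting predefined sensitivity and specificity goals. Ships the upstream
    M-mode preprocessing pipeline (3-second segmentation, pleural-line ROI,
    brightest-column M-mode reconstruction, 224x224 resizing), a model-agnostic
    classifier contract with a lightweight baseline, a downstream metadata
    subgroup audit (chi-squared and one-way ANOVA stratified by ground-truth
    class, with within-subgroup fragility indices), and a synthetic multicenter
    LUS generator for desk-scale testing of the whole protocol.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
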