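Package: xmpipe
Title: Chest X-Ray Normalization, Hardware-Mimicking Augmentation, and
    Robustness Evaluation
Version: 0.1.0
Authors@R:
    person("xmpipe", "developers", email = "xmpipe@example.org",
           role = c("aut", "cre"))
Description: Preprocessing and data-augmentation toolkit for chest
    radiograph classification across heterogeneous x-ray hardware.
    Implements an iterative histogram-modification normalizer anchored on
    the lung-field minimum intensity, the conventional baselines it is
    compared against (histogram equalization, contrast-limited adaptive
    histogram equalization, unsharp masking), physics-motivated
    contrast/sharpness/noise augmentation operators, a synthetic
    chest-phantom generator with ground-truth lung masks, and a robustness
    evaluation protocol (ROC AUC with DeLong variance and paired tests,
    Fisher p-value combination, repeated stratified splits,
    majority-class under-sampling, and single-axis perturbation sweeps).
    Reads raw stored pixel values from single-frame grayscale DICOM and
    8/16-bit grayscale PNG without applying display window/level.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    digest,
    glmnet,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
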