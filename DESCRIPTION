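Package: metacamr
Title: Consensus Ensembles of Class Activation Maps with ROAD Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ensembling visual explanations of convolutional image
    classifiers. Implements a registry of class activation mapping (CAM)
    methods (GradCAM and its variants, elementwise and layer-wise CAMs,
    perturbation-based ScoreCAM and AblationCAM, eigen methods, FullGrad and
    a random baseline), a consensus ensemble that keeps the top-k percent of
    pixels in agreement across component maps, adaptive threshold selection
    driven by the Remove-and-Debias (ROAD) pixel-perturbation metric with
    noisy linear imputation, a combinatorial group inclusion/exclusion
    experiment grid with the Cumulative Residual Effect summary statistic,
    and a self-contained synthetic fixture suite (planted-saliency scenes
    and a small trainable convolutional classifier) for testing without
    external model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
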