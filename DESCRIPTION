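Package: afse
Title: ANOVA-F Spectral Embedding Fusion for Histopathology Patch
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-class classification of cervical histopathology
    image patches by fusing deep convolutional and handcrafted texture
    features. Provides template-gated random-crop augmentation (sum of
    absolute differences matching plus random translation, rotation, zoom
    and brightness), local binary pattern and histogram-of-oriented-gradient
    descriptors, convolutional backbone feature extractors with a
    fine-tuning recipe, per-feature ANOVA F-value scoring with
    cumulative-weight selection, Laplacian-eigenmap spectral embedding with
    Nystrom out-of-sample extension, serial feature fusion keyed by
    combination codes, a fully connected softmax fusion subnet, feature
    quality diagnostics (chi-square, ANOVA-F and extremely-randomized-trees
    weight curves, sparsity), micro-averaged ROC/AUC evaluation, and seeded
    synthetic fixtures so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
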