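Package: cramnet
Title: Interpretable Dual-Branch Image Classifier with Recurrent Gated
    Channel Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Dual-branch convolutional classifier for two-class
    histopathology-style image patches, fused through a two-step
    sigmoid-gated channel-attention block with a residual connection,
    together with a full interpretability stack: branch-fused Grad-CAM
    saliency maps, superpixel Kernel SHAP attribution with an exact
    Shapley oracle, saliency-annotation agreement metrics (IoU, Dice,
    pointing game, normalized overlap), and confusion-matrix / ROC /
    McNemar evaluation. Includes a seeded synthetic histology image
    generator with planted ground-truth tumor masks so the whole
    pipeline runs end-to-end at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
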