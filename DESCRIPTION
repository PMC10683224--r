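Package: rgdfusion
Title: Radiomics, Graph and Deep Convolutional Feature Fusion for Lung
    Nodule Malignancy Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benign-malignant lung nodule classification on CT sub-volumes by
    the RGD fusion algorithm: 3D texture radiomics (volume local binary
    patterns, 3D histograms of oriented gradients, 3D gray-level co-occurrence
    matrices), five small convolutional feature extractors, a two-layer graph
    convolutional network over a model-divergence graph, focal-loss trained
    fusion heads, and an accuracy-weighted ensemble decision. Includes a
    synthetic nodule phantom generator, rating-based label derivation,
    patient-disjoint k-fold cross-validation, and the standard evaluation
    metrics, so the full pipeline runs at desk scale without external imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
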