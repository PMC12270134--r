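Package: qembed
Title: Neural Quantum Embedding and Fidelity-Kernel Classification for
    Expression Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid quantum-classical binary classification for transcriptomic
    biomarker studies. Implements exact statevector simulation of IQP/ZZ quantum
    feature maps, Neural Quantum Embedding (a classical network trained under a
    state-fidelity loss so that the two classes embed into near-orthogonal
    quantum subspaces), fidelity-kernel support vector classification fitted in
    the dual on precomputed Gram matrices, a variational quantum classifier with
    parity readout and parameter-shift gradients, classical SVC and neural
    network baselines, and an imbalance-aware evaluation protocol: PCA
    dimensionality reduction, stratified splitting, SMOTE oversampling,
    two-stage grid search, ten confusion-matrix metrics and per-metric
    comparative scoring. A synthetic-data generator emulates the statistical
    shape of the motivating renal-carcinoma metastasis cohorts so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    e1071,
    withr
Config/testthat/edition: 3
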