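Package: dynamilc
Type: Package
Title: Self-Supervised Attention-LSTM Models with Validated Saliency for
    Multivariate Brain Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns representations of multivariate ICA time courses by
    maximizing mutual information between sliding-window embeddings and the
    whole-sequence embedding (an InfoNCE objective), fine-tunes an
    attention-based two-level LSTM classifier for patient/control
    discrimination, and introspects trained models with integrated gradients
    and smoothgrad saliency.  Attributions are validated with a
    retain-and-retrain scheme (masking to the top salient cells, recomputing
    functional network connectivity, retraining an independent RBF-SVM) and
    characterized temporally via earth mover's distance between top-saliency
    densities and the uniform density.  Includes a synthetic cohort generator
    with planted connectivity and focal-event ground truth so the full
    pipeline is testable without access to clinical data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
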