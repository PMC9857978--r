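Package: medrec
Title: Medication Recommendation from Longitudinal EHR Visit Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-visit drug combinations from longitudinal electronic
    health records. A patient encoder with code-level and visit-level attention
    (GRU-based) summarises the visit history, a two-layer graph convolutional
    encoder embeds drugs over co-prescription and drug-drug-interaction graphs,
    and a patient-similarity memory retrieves drug information from the
    patient's own history and from similar patients. Training combines a DDI
    penalty, a multi-label margin plus binary cross-entropy objective, and an
    information-bottleneck constraint based on matrix Renyi alpha-entropy,
    optimised with Adam on a built-in reverse-mode autodiff tape. Includes a
    seeded synthetic-cohort generator with latent-condition structure, set
    based evaluation metrics (Jaccard, F1, PR-AUC, ROC-AUC, DDI rate), a
    bootstrap evaluation protocol, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
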