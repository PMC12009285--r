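Package: thermofuse
Title: Thermogram Lesion Segmentation and Ensemble Diagnosis with a
    Hybrid Rock-Hyrax/Dandelion Optimizer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for breast-thermogram analysis built around a hybrid
    derivative-free metaheuristic (RHDAO) that routes each candidate between
    rock-hyrax swarm updates and dandelion-algorithm sowing using a normalized
    fitness angle. Provides contrast preprocessing (CLAHE with an explicit
    clip-limit parameterization and global histogram equalization),
    optimizer-driven binary thresholding of hyperthermic lesions, three-branch
    deterministic feature extraction with weighted stacked fusion, a
    score-voting ensemble of small neural heads with metaheuristically tuned
    hyperparameters, a full confusion-matrix metric suite, and a seeded
    synthetic-thermogram phantom generator so the entire pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
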