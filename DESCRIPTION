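Package: feddis
Title: Federated Learning with Latent Distribution Information Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for cross-silo federated image classification
    under label-skew non-IID data. Clients federally train a convolutional
    variational autoencoder, expand each encoded image into 2d sigma points,
    estimate a per-class latent distribution, and exchange only those
    distribution parameters; every client then decodes fresh latent draws into
    synthetic images so that all local label distributions match the global one
    before federated training of the task classifier (FedDIS). Includes
    explicit-proportion and Dirichlet label-skew partitioners, earth mover's
    distance heterogeneity measures, privacy metrics (set distance, maximum
    structural similarity), the generated-vs-original training-loss gap, and a
    synthetic labeled-image generator so the full pipeline runs without
    external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
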