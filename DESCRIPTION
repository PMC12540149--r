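Package: nbiclass
Title: Fused Deep-Feature Classification of Narrow-Band Laryngoscopy Patches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for four-class classification of
    narrow-band laryngoscopy tissue patches (hypertrophic blood vessels,
    healthy tissue, IPCL-like vessels, leukoplakia). Provides a synthetic
    texture-patch generator emulating the 1,320-patch study layout, median
    filter preprocessing for salt-and-pepper noise, three convolutional
    feature extractors (an AlexNet-style network, a SqueezeNet-style
    fire-module network, and a capsule network with dynamic routing) whose
    embeddings are fused by concatenation, an autoencoder latent-space
    classifier, and the Osprey Optimisation Algorithm as a bounded
    continuous metaheuristic for hyperparameter tuning. All networks are
    implemented as plain matrix computations with analytic gradients, so
    the pipeline runs on a single CPU at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
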