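Package: bionanofp
Title: Adsorption Free-Energy Fingerprints of Nanomaterials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the bionano interface through
    adsorption free-energy fingerprints: extraction of adsorption free
    energies from potential-of-mean-force profiles with window-based
    uncertainty, agglomerative (Ward) and k-means clustering of small
    biomolecules by their binding profiles across nanomaterials, selection
    of representative probe molecules, regression models (linear,
    AdaBoost.R2 with depth-3 tree learners, one-hidden-layer neural
    network) that predict the full fingerprint from a handful of probes,
    repeated 70/30 shuffle-split validation including a leakage-free
    variant, and grouping of nanomaterials from measured versus predicted
    fingerprints. A synthetic-data generator with planted group structure
    supports end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    rpart,
    mclust,
    pracma,
    ape,
    withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
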