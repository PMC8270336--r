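Package: flavoptim
Title: Chemometric Optimization of Ultrasonic Flavonoid Extraction
Version: 0.1.0
Authors@R: person("flavoptim", "maintainers", email = "maintainers@flavoptim.org", role = c("aut", "cre"))
Description: Tools for modelling and optimizing ultrasound-assisted extraction
    of plant flavonoids: four-factor three-level Box-Behnken designs and
    factor coding, full second-order response-surface models with Type-III
    ANOVA and lack-of-fit testing, a single-hidden-layer feed-forward neural
    surrogate (tansig/purelin) with Garson weight-decomposition importance,
    real-coded genetic-algorithm and particle-swarm optimizers over box
    constraints, CART/random-forest/gradient-boosted-tree factor ranking,
    rutin standard-curve quantification and radical-scavenging statistics,
    and first-order (Fick) extraction kinetics. Ships a published 29-run
    design and network-weight table as plain-text fixtures, plus seeded
    synthetic-data generators with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
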