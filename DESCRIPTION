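Package: mitomotor
Title: Censored Mixture Models for Motor Latency and Mitochondrial
    Bioenergetics Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for gut-microbiome by alpha-synuclein mouse
    studies combining motor behaviour and striatal mitochondrial physiology.
    Fits a right-censored lognormal mixture model to latency-to-complete
    motor-test data by maximum likelihood with parametric-bootstrap
    confidence intervals and graphical model assessment; provides rank-based
    group inference (Kruskal-Wallis with Conover or Dunn post-hoc tests and
    Benjamini-Hochberg adjustment); computes mitochondrial bioenergetics
    indices (plate-normalized enzymatic activities, Mitochondrial Health
    Index, Mitochondrial Respiratory Capacity, qPCR-based mtDNA copy number
    and density); derives respiration states and respiratory control ratios
    from injection-phased oxygen-consumption traces; and includes seeded
    synthetic-data generators emulating every input so the full pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
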