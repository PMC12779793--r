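Package: miebl
Title: Bayesian Selection of Mastery Criteria for Discrete Trial Training
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for choosing performance (mastery) criteria in discrete
    trial training using beta-binomial conjugate inference under a Jeffreys
    prior. Given n assessment trials with x correct responses, the package
    computes the posterior probability that a student's latent true mastery
    level meets a desired threshold, credible lower bounds, and posterior
    means; builds per-criterion tables and five-statement practitioner
    reports; overlays posterior densities for competing criteria; inverts
    the computation to plan the number of trials or required correct count
    for a target confidence; and validates operating characteristics
    (misclassification among students meeting a criterion) by Monte Carlo
    simulation. Trial-level session records in CSV can be aggregated into
    counts per student, skill and session.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
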