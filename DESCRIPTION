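Package: rescuekit
Title: Evolutionary Rescue in Periodically and Quasi-Periodically Fluctuating Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic eco-evolutionary modelling of evolutionary rescue for a
    density-regulated population that alternates between a harsh environment, in
    which the wild type declines, and a favourable environment, in which it
    grows. Provides an exact event-driven (Gillespie) simulator of the coupled
    wild-type and generalist-mutant birth-death process under logistic, Gompertz
    or Richards density regulation, together with matching analytical
    predictions: master-equation extinction probabilities per environmental
    phase, the cycle-count law and mean total extinction time, fixation
    probabilities of mutant lineages in the time-varying background, rescue
    probabilities from de novo mutation and standing genetic variation, and the
    mean appearance time of the rescuing mutant. Includes a sweep runner and a
    command-line interface for reproducing figure-style experiments at
    configurable replicate counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
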