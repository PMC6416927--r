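Package: dupdyn
Title: Dynamics of Duplicate Gene Retention After Whole-Genome Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how duplicate genes retained after
    whole-genome duplication (WGD) diverge in expression and cis-regulation.
    Provides maximum-likelihood ancestral state reconstruction of discretized
    expression quartiles and binary binding-site presence on gene family trees
    under a continuous-time Markov model with repeated-restart consensus
    calling; classification of duplicate pairs by retention of the ancestral
    state (both, one, or neither copy); permutation z-score grids and
    asymmetry statistics with grouped Bernoulli nulls; three-state kinetic
    ODE models of ancestral-state loss fit by maximum likelihood with
    likelihood-ratio model selection; and linear modelling of per-group
    duplicate-retention odds with F-maximizing backward elimination and
    leave-one-out robustness. Includes seed-deterministic synthetic data
    generators so the full pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml
Config/testthat/edition: 3
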