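Package: dolgame
Title: Division of Labour in n-Player Task-Selection Games under Social and
    Individual Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation and adaptive-dynamics analysis of a
    continuous-trait division-of-labour game. A population of agents splits
    effort between two collective tasks and inactivity; group benefits couple
    multiplicatively across tasks while costs are individual. The same game is
    iterated under payoff-biased imitation with Gaussian exploration (social
    learning) and under a binned cross-learning reinforcement rule (individual
    learning). A numerical adaptive-dynamics layer locates and classifies
    singular strategies (ESS, branching point, repeller) and predicts the
    qualitative regime (fully specialised, branching, uniform), which can be
    compared against simulated trajectories, including the emergence of
    inactive subgroups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
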