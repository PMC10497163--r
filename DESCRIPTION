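Package: metamerlab
Title: Task Metamers for Tile-Revealing Meta-Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Procedural generators for rule-based 7x7 two-colour board
    distributions, low-order board statistics, and a "task metamer"
    construction that trains a masked-tile conditional network on a rule's
    boards and draws statistically matched boards by Gibbs sampling.
    Includes the tile-revealing episodic environment, a nearest-neighbour
    heuristic baseline with z-score performance normalisation, four
    policy/value network architectures (LSTM meta-learner, episodic
    planning network, transformer, relational similarity network) trained
    with advantage actor-critic, and an experiment harness for
    abstract-versus-metamer comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
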