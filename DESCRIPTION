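Package: permex
Title: Asynchronous Replica Exchange with Infinite Swapping via Matrix Permanents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A noncohort (asynchronous) replica-exchange Monte Carlo engine for
    ensembles whose moves have unequal computational cost. K workers act on N > K
    ensembles on a deterministic discrete-event virtual clock; whenever a worker
    finishes, states are exchanged among the currently unoccupied ensembles either
    by finite pair swapping or by infinite swapping, where all state-to-ensemble
    permutations are sampled at once with fractional weights obtained from a
    doubly stochastic probability matrix of matrix permanents (exact
    Balasubramanian-Bax-Franklin-Glynn evaluation, with block decomposition and a
    polynomial-time staircase fast path). The engine drives replica exchange
    transition interface sampling (RETIS) path ensembles, with built-in model
    systems (a memoryless single-variable stochastic process, an underdamped
    Langevin double well, and a discrete validation toy) and analysis tools for
    crossing probabilities, fluxes, rates, block errors and efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
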