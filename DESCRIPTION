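Package: neuralca
Title: Coherent Structures in a Stochastic Neural Cellular Automaton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and multiscale analysis of a three-state (refractory,
    quiescent, spiking) Markov-chain cellular automaton for neural tissue on a
    ring, coupled through a Mexican-hat synaptic kernel. Provides the
    stochastic and deterministic microscopic dynamics, interface (threshold
    crossing) theory for stationary bumps, multi-bumps and travelling waves
    with closed-form linear stability, approximate probability mass functions
    for the coherent states, and an equation-free coarse time-stepper
    (microstructure-aware lifting, restriction, damped Newton and
    pseudo-arclength continuation) for coarse-grained bifurcation analysis,
    including heterogeneous (cosine-modulated) coupling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
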