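Package: snnkit
Title: Modular Spiking Neural Networks with Reward-Modulated Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A composable toolkit for simulating spiking neural networks and
    training them with local, reward-modulated plasticity. Models are described
    by declarative, serializable blueprints (graphs of soma pools, traced
    synapses, encoders and decoders) and executed deterministically. Includes
    leaky integrate-and-fire, adaptive exponential, and Hodgkin-Huxley soma
    models, traced-current synapses with per-connection delays, a three-factor
    quadruplet spike-timing-dependent plasticity rule with eligibility traces
    and structural growth/pruning, grid-cell-like population encoders and
    saturable trace decoders, a self-contained cartpole environment, an online
    training loop driven purely by a sparse terminal reward, and a spike-train
    fidelity harness based on the ISI-distance and SPIKE-distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tibble,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
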