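Package: ctboolnet
Title: Continuous-Time Boolean Networks: Stochastic Simulation and Exact Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of continuous-time Markov dynamics on Boolean
    networks. Models are written in a small rate-annotated logic language (BND-style
    text files) in which every node carries an activation and an inactivation rate
    expression; trajectories are generated with the Gillespie (kinetic Monte-Carlo)
    algorithm on the asynchronous Boolean state space. The package estimates
    time-windowed network-state probabilities, Shannon entropy, transition entropy and
    Hamming-distance distributions with Monte-Carlo errors, estimates indecomposable
    stationary distributions from whole trajectories and clusters them by
    support-overlap similarity. For small networks an exact master-equation oracle
    (matrix exponentials, generator spectra, transition-graph analysis) provides ground
    truth. Includes example models (a single-cycle toy network, a p53-Mdm2 DNA-damage
    network with a two-level p53, the 10-node mammalian cell-cycle logic) and a
    command-line driver writing CSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    parallel
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
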