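Package: heterosim
Title: Boolean Gene-Regulatory-Network Simulation of Heterosis and Hybrid Incompatibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of diploid Boolean gene regulatory
    networks under environment-dependent selection. Populations of networks
    adapt to switch pre-defined gene modules on and off in response to clamped
    environment nodes, then diverge in isolation; periodic hybridization
    between the diverged populations exhibits hybrid vigor (heterosis) and,
    after prolonged separation, a speciation-like collapse of hybrid fitness.
    Provides scale-free-like founder network generation with triad formation,
    synchronous attractor dynamics, a Metropolis-Hastings selection scheme,
    and a decomposition of hybrid fitness into dominance, over-dominance,
    under-dominance and pairwise epistasis (positive, negative, incompatibility)
    mechanisms, with run pooling aligned on the collapse event.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
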