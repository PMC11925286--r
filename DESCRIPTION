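Package: vaxcampsim
Title: Coupled Vaccine-Opinion Diffusion and Epidemic Simulation with
    Campaign Targeting Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of the interplay between vaccine-opinion
    formation and epidemic spread on small-world contact networks. A
    complex-contagion opinion stage, in which competing negative and positive
    vaccine sentiment diffuses through external campaigns and social
    influence, determines vaccination uptake; a discrete-time stochastic SIR
    stage then measures the final epidemic size among unvaccinated agents.
    Seven positive-campaign targeting strategies (static random, betweenness
    centrality based, and dynamic neighbourhood-information based) are
    implemented together with replication, parameter sweeps, diagnostics for
    anti-vaccine cluster structure, and tidy accessors and plots for all
    result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
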