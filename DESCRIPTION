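Package: metacomdyn
Title: Multitrophic Metacommunity Dynamics on Stochastic Dynamic Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multitrophic metacommunities on spatially explicit,
    temporally dynamic landscapes of temporary habitat sites. Landscapes are
    modular random geometric graphs whose sites switch between active and
    inactive states on stochastically jittered yearly schedules. Regional food
    webs are generated with controlled trophic coherence (a temperature
    parameter), local communities follow generalized Lotka-Volterra dynamics
    whose growth rates are parameterized by linear programming to yield
    feasible, Lyapunov-stable equilibria, and dispersal among active sites is a
    continuous-time Markov chain simulated with the first-reaction method with
    instantaneous equilibrium recomputation and secondary-extinction cascades.
    Includes alpha/beta/gamma persistence and biomass metrics, asynchrony
    sensitivities, and standardized effect-size regressions with AICc
    all-subsets model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
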