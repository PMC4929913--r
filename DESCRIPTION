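Package: sceneforage
Title: Agent-Based Foraging Simulation with Scene-Memory Rule Switching
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a memory-limited forager on a planar field of point
    sites. The focal model switches between an exploitation rule (move to the
    nearest detected site) and an exploration rule (move to the farthest
    detected site) whenever the count of currently visible sites matches a
    short-lived remembered scene, producing emergent weak home-range
    behaviour. Includes memory-free control models (fixed exploitation, fixed
    exploration, random choice) and a spatial working/reference-memory
    control, together with the movement statistics used to characterise the
    trajectories: distinct-site visit counts, per-site revisitation
    distributions with discrete power-law versus exponential maximum
    likelihood fits arbitrated by Akaike weights, mean-squared displacement
    curves, and trajectory density maps. Seeded Monte Carlo experiment
    runners and a small command-line interface support reproducible
    parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
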