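Package: staghunt
Title: Embodied Stag-Hunt Simulations with Neuroevolution of Robot Controllers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulations of a two-player stag-hunt coordination
    game played by embodied agents: differential-drive robots with ray-based
    proximity sensors and a typed camera, each driven by a sigmoid multilayer
    perceptron whose 410 connection weights evolve under either elitist
    (10+10) or Wright-Fisher (fitness-proportionate) selection. Includes a
    network-duplication operator enabling leader-follower division of labor,
    multi-phase replicate protocols (boar-hunter pre-evolution followed by
    payoff reinstatement), and analysis tools: hunting-strategy profiles,
    equilibrium-transition detection, a closed form for coordination failure
    of mixed strategists, mutant fitness-landscape screening, and a one-tailed
    Mann-Whitney U test with exact small-sample enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
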