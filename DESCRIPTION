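Package: divpace
Title: Habitat-Specific Diversification Rates Through Time for Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Episodic birth-death inference on a 1-My time grid with horseshoe
    Markov random field (HSMRF) shrinkage priors, congruence-class robustness
    checks via the pulled diversification rate, lineage-specific
    birth-death-shift detection with discretized-lognormal rate categories,
    and hidden-state state-dependent speciation/extinction (HiSSE-2) inference
    with a posterior fold-change statistic. Includes forward birth-death tree
    simulators with incomplete sampling, habitat and feeding-mode trait
    classification utilities, MCMC samplers with Kolmogorov-Smirnov
    convergence checks, and a configuration-driven analysis pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), deSolve, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
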