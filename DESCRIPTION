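Package: actinf
Title: Active Inference Simulations of Working Memory, Attention and Salience
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-state active inference (Markov decision process)
    simulator for studying working memory, attention and salience.
    Categorical generative models are specified by likelihood (A),
    transition (B), preference (C) and initial-state (D) arrays, composed
    into deep temporal hierarchies in which higher levels evolve over
    slower timescales.  Belief updating is implemented as a gradient
    descent on variational free energy, policy selection by expected free
    energy under a precision (inverse temperature) parameter, and the
    package derives simulated neuronal observables from the update
    dynamics: unit rasters, event-related potentials as rates of belief
    change, phasic dopamine as precision updates, and reaction times.
    Ships a two-level delay-period retrocue task and a single-level
    orientation maintenance task, plus scripted experiments for reaction
    time scaling, context- and load-dependent evoked responses, precision
    lesions, and volatility-driven forgetting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
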