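Package: coadapt
Title: Agent-Based Simulation of Retinotopic Map Formation with Growth
    Cone Co-Adaptation
Version: 0.1.0
Authors@R:
    person("Jonas", "Keller", email = "jonas.keller@posteo.net",
           role = c("aut", "cre"))
Description: Stochastic agent-based model of topographic axon guidance in
    the retinotectal system. Growth-cone terminals carrying EphA receptor
    and ephrin-A ligand sensors perform a biased random walk on a target
    field and minimize a guidance potential computed from total forward
    and reverse signaling (fiber-target, fiber-fiber and cis
    interactions). Sensor dynamics implement 'co-adaptation', a common
    multiplicative adaptation coefficient applied to both sensor species
    together with a Hookian resetting force, which desensitizes terminals
    while preserving the ephrin-A/EphA ratio that encodes topographic
    identity. Includes scenario builders for mapping, in-silico gap
    assays (single- and double-cue), tectal entry, EphA3 knock-in and
    regeneration-style experiments, quantitative map metrics, and a
    fluorescence-image fiber-counting quantifier for gap assays with a
    synthetic image generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
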