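Package: bcmdyn
Title: Dynamical Analysis of the BCM Synaptic Plasticity Rule
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the Bienenstock-Cooper-Munro (BCM) synaptic
    modification rule as a dynamical system. Provides a hybrid stochastic
    simulator in which stimuli switch as a Markov jump process, the averaged
    (mean-field) equations in response space, closed-form stability theory for
    the selective equilibria (Routh-Hurwitz Hopf criteria for one neuron and
    for a pair of laterally inhibiting neurons), and numerical machinery for
    bifurcation analysis: equilibrium sweeps, Hopf bisection, limit-cycle
    location, Floquet multipliers, Poincare sections, maximal Lyapunov
    exponents, and a relative-selectivity summary statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
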