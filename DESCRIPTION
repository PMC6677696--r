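Package: dggsim
Title: Dynamical Graph Grammars: Rule-Based Modeling with Operator-Algebra Semantics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative modeling stack for rule-based stochastic biological
    models: pure chemical reaction rules, parameterized rewrite rules,
    ODE-bearing rules, and labeled-graph rewrite rules (dynamical graph
    grammars), with chemical-master-equation operator semantics. Includes a
    brute-force generator-matrix oracle on truncated state spaces, an exact
    generalized Gillespie simulator and a hybrid jump-ODE simulator with
    integrated-hazard event timing, a symbolic engine for normal-form
    products and commutators of graph rewrite operators over binary
    vertex-label and edge-occupancy state variables, graded/stratified
    graph and abstract-cell-complex structures with slice-rule lowering,
    and worked grammars for stem-cell division, triangular mesh refinement,
    and cortical microtubule dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    jsonlite,
    xml2,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
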