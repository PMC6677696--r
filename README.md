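# dggsim: dynamical graph grammars with operator-algebra semantics

Biological development keeps changing its own playing field: cells divide
and rewire their contacts, microtubules grow, shrink and bundle, meshes
that discretize a growing tissue must be refined on the fly. `dggsim` is
an R package for modeling such systems *declaratively*, as collections of
rewrite rules — pure chemical reactions, parameterized term rewrites,
ODE-bearing rules, and labeled-graph rewrite rules (dynamical graph
grammars) — all sharing one mathematical semantics: each rule denotes an
operator built from creation/annihilation generators, and a model's
master-equation generator is the sum of its rule operators,

$$W \;=\; \sum_r \big(\hat W_r - D_r\big), \qquad
  \hat W_r = k_r \prod_{\beta}(\hat a_\beta)^{n^{(r)}_\beta}
                 \prod_{\alpha}(a_\alpha)^{m^{(r)}_\alpha}, \qquad
  D_r = \mathrm{diag}(\mathbf 1 \cdot \hat W_r),$$

driving the chemical master equation $\dot p = W p$. For graph rules the
generators act on binary vertex-label and edge-occupancy state variables,
with erasure operators implementing vertex deallocation cleanup, and sums
over pairwise-distinct vertex indices.

The package is aimed at researchers in systems/developmental biology and
at anyone studying rule-based stochastic processes who wants the
*semantics* to be a first-class, checkable object rather than an informal
convention. It provides:

* a textual rule DSL (`.dgg` files) plus S4 rule and state classes;
* an exact generalized Gillespie simulator over all rule variants, and a
  hybrid jump–ODE simulator with exact integrated-hazard event timing;
* a brute-force master-equation oracle on truncated state spaces
  (`Matrix`-based, `expm` for $p(t)$);
* a symbolic engine for normal-form products and commutators of graph
  rewrite operators, validated exactly against the matrix oracle;
* graded/stratified graphs and abstract cell complexes, strata
  extraction, and lowering of slice-level rules to gated ordinary rules;
* worked grammars: stem-cell division, triangular mesh refinement,
  cortical microtubule dynamics, breakable-spring mechanics.

## A worked example

```r
library(dggsim)

## a birth-death process, straight from DSL text
rs <- parseRuleset(c(
  "birth: 0 -> A with 2",
  "death: A -> 0 with 1"))

## oracle: build W on {0..20} and check conservation
space <- enumerateStates(species = "A", caps = 20)
W <- buildGenerator(rs, space)
max(abs(Matrix::colSums(W@mat)))
#> max |column sum of W| = 0

## SSA endpoints vs the master equation at t = 2
pt <- evolveDistribution(W, c(1, rep(0, 20)), 2)
set.seed(1)
ends <- vapply(1:10000, function(i) simulateSSA(rs, c(A = 0), 2)$state[["A"]], numeric(1))
0.5 * sum(abs(tabulate(ends + 1, 21) / 10000 - pt))
#> TV(SSA at t=2, expm(Wt) p0) = 0.008
```

The total-variation distance 0.008 says the stochastic trajectories and
the deterministic probability flow are two views of the same generator.
The symbolic layer exposes that generator term by term:

```r
relabel <- parseRuleset(c(
  "graph ab {", "  lhs { 1 A }", "  rhs { 1 B }",
  "  rate 1", "  cleanup full", "}"))
opFromRule(relabel[["ab"]])
#> NormalFormOperator with 1 term(s)
#>    +1 a[v:1:A] ahat[v:1:B] (k=1)
diagonalPart(relabel[["ab"]])
#> NormalFormOperator with 1 term(s)
#>    +1 n[v:1:A] (k=1)
length(opCommutator(opFromRule(relabel[["ab"]]), opFromRule(relabel[["ab"]])))
#> [1] 0
```

The inflow operator annihilates an `A` label and creates a `B` on the
same vertex (summed over all vertices); its outflow diagonal is the
`A`-counting number operator; an operator commutes with itself, and the
canonicalized commutator is the *empty* sum, not a pair of uncancelled
terms. Finally, a structural model — refining one triangle of a graded
mesh to quiescence:

```r
mesh <- meshRefinementGrammar(lmax = 1)
out <- runToQuiescence(mesh, makeTriangleMesh(1), seed = 1)
meshLevelCounts(out$state, 1)
#> refined triangle: 6 vertices, 9 edges, 4 sub-triangles at level 1
```

See `vignettes/dynamical-graph-grammars.Rmd` for the model semantics,
parameter choices and known limitations.

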