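---
title: "Dynamical graph grammars: models, semantics, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical graph grammars: models, semantics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dggsim)
```

# The modeling stack

`dggsim` implements a family of declarative, rule-based modeling languages
of increasing expressive power, all sharing one mathematical semantics:
each rewrite rule denotes an operator, and a model's generator is the sum
of its rule operators.

**Pure reaction rules.** A rule
$\sum_\alpha m_\alpha A_\alpha \xrightarrow{k} \sum_\beta n_\beta A_\beta$
rewrites a multiset of species. Its probability-inflow operator is the
normal-ordered monomial
$\hat W_r = k \prod_\beta (\hat a_\beta)^{n_\beta} \prod_\alpha (a_\alpha)^{m_\alpha}$
in species creation/annihilation operators; annihilation encodes the
mass-action falling factorial $n(n-1)\cdots(n-m+1)$. With the outflow
diagonal $D_r = \mathrm{diag}(\mathbf 1\cdot\hat W_r)$, the generator
$W = \sum_r (\hat W_r - D_r)$ has zero column sums (probability
conservation) and drives the chemical master equation (CME)
$\dot p = W p$.

**Parameterized rules.** Terms carry numeric parameters,
`stemcell[x, V] -> TAcell[x+dx, V/2], stemcell[x-dx, V/2]`, with a rate
that factors into an LHS-only propensity and a normalized conditional
sampler of RHS-only variables. The factoring is *required* at the rule
level (a design decision): it keeps the semantics of the stochastic
firing unambiguous, whereas inferring the factorization from a joint
density would be implementation-defined.

**ODE-bearing rules.** A rule whose LHS and RHS are the same term list may
attach drift expressions $\dot x_{p} = v_p([x_k])$ to continuous
parameters; between discrete events all matches of all ODE rules
contribute additively to the flow.

**Graph rewrite rules.** States become labeled *pool graphs*: an indexed
universe of vertices with binary activity (exactly one label when active),
binary directed edge occupancies, and continuous per-vertex parameters
stored beside the discrete label. The invariants are (a) every vertex has
0 or 1 labels present and (b) present edges connect two active vertices.
A rule lists numbered vertices shared between its two sides: kept vertices
retain their state index (and any edges the rule does not mention),
LHS-only vertices are deallocated, RHS-only vertices are freshly
allocated. Undirected models are encoded as symmetric directed edge
pairs, and an undirected pattern edge requires both directions.

# Operator semantics over binary state variables

The graph-rule semantics acts on one bit per (vertex, label) pair and one
bit per ordered vertex pair. On a single bit the generators are the
creation $\hat a$, annihilation $a$, the projectors
$N = \hat a a$ and $Z = I - \hat a a$, and the erasure $E = Z + a$ that
clears a bit unconditionally. These six nonzero maps (including
$F = \hat a + N$, which arises in products) are exactly the *conditional
bit assignments* "require 0/1/anything, then write 0/1"; they are closed
under composition with zero. Consequently a normal-form term carries
exactly one generator per touched bit, a scalar weight with a symbolic
rate product, a set of abstract vertex indices summed over distinct
concrete tuples, and optional symbolic *erasure ranges*
$\prod_{i \notin X} E_{p i} E_{i p}$ implementing deallocation cleanup
without enumerating the index universe.

A rule operator is transcribed as: erasure ranges for deleted vertices
(full cleanup), RHS edge creations, prohibited-edge $Z$ factors, RHS label
creations, LHS edge annihilations, LHS label annihilations. Two
bookkeeping refinements matter:

* **Allocation is explicit.** A reserved null label marks free vertices:
  creating a vertex consumes the null bit, deleting one restores it. This
  makes the outflow identity exact: the diagonal operator of a rule equals
  the inflow operator of the rule LHS $\to$ LHS (with freed/needed null
  labels carried along), realized as
  $\mathrm{diag}(\mathbf 1 \cdot \hat W_r)$ on every physical (one-hot)
  state. Without the null label the identity fails for allocating rules
  on a finite index pool. A side effect worth knowing: two rules that
  touch disjoint species but both allocate/deallocate interact through
  the shared free-index pool, so their commutator need not vanish at the
  level of indexed states (it vanishes after quotienting by vertex
  naming). Pure conversion reactions are encoded as relabelings of kept
  vertices, so disjoint-species conversions commute exactly.
* **Edge-creation hygiene.** A rule that creates an edge between two kept
  vertices must declare that edge prohibited ($\bar g$) on its LHS;
  creation on an occupied bit is zero, so without the prohibition the
  operator would silently drop those firings while an operational
  (idempotent) engine would not. Symmetrically, an RHS-prohibited edge
  between kept vertices that the rule does not delete must be declared
  absent on the LHS too (kept edges persist, so the RHS condition is
  decidable before firing). The fixture generator enforces both
  conventions, and the validator warns when a required and prohibited
  edge coincide (the operator then vanishes, since $aZ = 0$).

**Products and commutators.** The product of two normal-form sums over
distinct index tuples is expanded by case-splitting on every pattern of
index identification between the two operands; per case, per-bit
generators compose (possibly annihilating the term), erasure ranges
materialize on the explicit bits they cover and record them in exclusion
sets, and the result is canonicalized. Canonical form minimizes the term
serialization over index permutations, searched only within
automorphism-ambiguous signature classes after two rounds of
neighborhood refinement; this realizes equality up to index renaming
(subpermutation invariance) and makes commutator cancellation effective.
The product algorithm is validated exhaustively against an explicit
matrix oracle (exact integer equality on pools of up to 3 vertices),
which is the appropriate ground truth given that the closure theorems are
stated abstractly.

**Realization.** `realizeOperator()` instantiates abstract index sums over
all distinct tuples of a small pool and builds the sparse matrix by
vectorized bit arithmetic on integer-encoded states. The matrix oracle in
`cme_oracle` takes the *operational* route instead — enumerate states,
match, fire — so the two routes are independent; their agreement is a
test, not a construction.

# Simulation

`simulateSSA()` is an exact generalized Gillespie algorithm over all
discrete rule variants: the full match list is recomputed after every
firing (correctness first; incremental matching is a known optimization we
deliberately do not attempt), waiting times are exponential in the total
propensity, and matches are ordered tuples, so a symmetric LHS fires at a
rate including its automorphism multiplicity — consistent with the
distinct-ordered-tuple sum convention and with mass-action $n(n-1)$
combinatorics. Engines that divide by symmetry will disagree by exactly
that factor.

`simulateHybrid()` alternates deterministic flow and jumps without
splitting error in the event times: the cumulative hazard
$H(t) = \int \lambda_{\mathrm{tot}}(x(s))\,ds$ is co-integrated with the
state by `deSolve::lsodar` and the next event fires when $H$ crosses an
Exp(1) threshold (root-finding), which samples the exact inhomogeneous
waiting time. With zero drift this reduces to plain SSA; with zero
discrete rates it is a pure ODE integration.

Determinism: a single RNG stream, seeded once per run; per event the draw
order is waiting-time (or hazard threshold), instance selection, RHS
samples. Identical seeds reproduce identical event logs. A configurable
`maxEvents` guard bounds runaway ("sorcerer's apprentice") models rather
than restricting rate functions.

# The truncated-state-space oracle

`enumerateStates()` enumerates either copy-number vectors under per-species
caps or all labeled-pool-graph configurations over a fixed small vertex
universe (filtered by the state invariants). Truncation policy: probability
flowing above the caps is dropped (absorbing loss), not reflected; the
conservation tests therefore use models and caps with negligible boundary
flux, and a refinement test checks that enlarging caps moves interior
probabilities by less than $10^{-8}$. The matrix exponential uses
`Matrix::expm`. Rules that allocate vertices contribute one transition per
choice of free target index, matching the index sum of the operator
semantics; note that the SSA's LIFO allocator picks a *specific* free
index, so oracle-vs-SSA distribution comparisons use relabel-only models
where the two agree state-by-state.

# Graded and stratified structures

Slice kinds constrain vertex labels `l` (refinement level) and/or `d`
(stratum dimension): graded graphs change level by at most one per edge
(directed: 0 or +1); stratified graphs direct edges from higher to lower
dimension (the undirected homomorphism imposes no edge constraint, so the
kind distinction is meaningful only for directed graphs — the validator
accepts all undirected stratified edges by design); abstract cell
complexes drop dimension by exactly 0 or 1; the graded-stratified and
graded-cell-complex combinations additionally forbid level and dimension
from changing along one edge. `extractStrataGraph()` deletes
inter-dimension edges and takes connected components; the strata DAG's
edges carry the neutral relation "contact" — disambiguating boundary
versus inside would need constraints we do not attempt.

`lowerSliceRule()` translates a rule written at the slice level (levels
dropped from vertices, level increments carried on edges) into an ordinary
graph rule: level variables are restored by propagating increments through
the pattern, and the rate is multiplied by indicator gates that vanish
whenever the LHS or RHS labeling violates the kind's predicate. The LHS
gate can be disabled when the initial state is certified valid. The
slice-aware matcher and the lowered rule take different code paths yet
produce identical seeded event logs — the commutation of implementation
with semantics that the design requires — and gated runs keep every
intermediate state validator-clean.

# The worked grammars

**Stem-cell division** (`stemCellGrammar()`): one parameterized rule; the
propensity $\hat\rho(V)$ defaults to the Hill form $V^h/(V^h+K^h)$ with
$h = 4$, $K = 1$ (the saturating shape is a standard size-control choice;
the form is configurable because the literature does not pin one down).
The displacement is Gaussian with scale $c\,V^{1/d}$ and the daughters
move by exactly opposite offsets, so the dynamics is Galilean-invariant
and the daughter midpoint is the mother position; volume is conserved
exactly per firing.

**Triangular mesh refinement** (`meshRefinementGrammar()`): four graded
graph rules, one per count of already-refined sides (0–3). Refinement
keeps the three level-$l$ corners, allocates level-$(l+1)$ corner copies
and side midpoints, builds the four sub-triangle cliques at the new level
(6 vertices, 9 edges), connects corners to copies by level-raising edges,
and deletes the level-$l$ side edges — which is what makes a refined side
recognizable to neighbors and prevents re-firing; the 3-refined-side rule
additionally needs prohibited mid–mid edges to be re-firing-safe. All
rules preserve graded validity. *Known limitation:* the printed source for
these rules is not recoverable, and this reconstruction is exact for one
refinement sweep of a mesh (each triangle refined once, side-sharing
neighbors handled correctly, $4T$ triangles from $T$). Deeper recursion
can duplicate corner copies when two triangles share only a corner;
handling that requires retaining sub-level strata beyond the graded
"frontier", which we leave out of scope. Demos and tests gate refinement
depth with `lmax`.

**Microtubules** (`microtubuleGrammar()`): fibers are chains of segment
super-particles with 2-D position and unit orientation and the four-valued
status label {internal, grow_end, retract_end, junct}. Rules: nucleation
(+2 segments), growth (+1), retraction (−1, full cleanup), catastrophe and
rescue (label switches, 0), and zippering: a growing end within capture
radius $\delta$ of a non-adjacent internal segment at line angle below
$\theta_c$ becomes a junction attached to that segment and spawns a new
growing end aligned (up to sign) with it (+1). Geometry enters only
through indicator gates in the rate expression, keeping the rule itself
structural. Default rates (nucleation 0.05, growth 1, retraction 1.5,
switching 0.3, zippering 0.2, $L = 0.5$, $\theta_c = \pi/5$,
$\delta = 0.6$) are chosen once to put the system in the *bounded* regime
of dynamic instability — shrinkage moderately dominating growth, the
experimentally typical interphase situation — so that fiber populations
reach a finite quasi-steady state; they are free parameters of the model,
not fitted quantities. The choice matters structurally: a zippered branch
is anchored at a junction and has no retracting end, so growth-dominated
parameters cascade into unbounded bundling. Collision-induced
catastrophe, severing, and bending are out of scope. Two-segment fibers
cannot retract (retraction needs an internal segment), a deliberate floor
that stands in for a minimal stable seed.

**Breakable springs** (`springEnergy()`, `springDriftModel()`): each pair
potential is $\tfrac12 k\,c\,[(|x_p-x_q| - l)^2 - \Delta l^2]$ with
$c \in \{0,1\}$ chosen to minimize the energy, i.e. the spring is intact
exactly while the bracket is non-positive; both branches meet at zero at
stretch $l + \Delta l$, making the energy continuous at breaking, and
broken springs are force-free. Coincident endpoints get zero force by
convention. Overdamped relaxation $\dot x = -\nabla V$ is expressed as a
three-term ODE rule (spring, two nodes) whose repeated variables tie the
spring's endpoint ids to node terms — one match per spring.

# What the synthetic fixtures do and do not show

The random fixtures (rulesets, pool graphs, slice graphs) are built
construct-by-predicate, so they always satisfy their validators; they
exercise the engine's bookkeeping (invariant preservation, conservation,
operator closure) over a broad structural range, at small sizes where the
brute-force oracles are exact. They are not biological data: passing
these tests says the *semantics* is implemented correctly, not that any
particular rate choice reproduces a measured system. Problem sizes used
throughout (state spaces up to a few hundred states, pools of 2–3
vertices for exact operator checks, $10^4$-sample stochastic comparisons,
$10^4$-event structural runs split over four replicates) were chosen so
that every check is exact or has standard-error-calibrated tolerances.

# Degenerate inputs and tie-breaking

Empty rule sides are legal everywhere (the empty rule is the identity
operator times its rate). Deallocating an inactive vertex is a warning
no-op (erasure on empty is identity). A vertex deleted and a vertex
created by one firing never share an index within that firing. Freed
indices are reused LIFO; vertex identity over time is its index while
continuously active, and the event log records enough (rule, match,
samples) to disambiguate reuse post hoc. Matching visits pattern vertices
in a connectivity-guided order and binds variables before checking
expression-valued slots; equality of bound numerics uses a relative
tolerance of $10^{-9}$.
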