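#' @import methods
#' @importFrom stats rexp runif rnorm setNames
#' @importFrom utils head tail
NULL

## ---------------------------------------------------------------------------
## Rule classes
## ---------------------------------------------------------------------------

#' Pure mass-action reaction rule
#'
#' A multiset-to-multiset rewrite rule with nonnegative integer
#' stoichiometries and a nonnegative (numeric or symbolic) rate constant.
#'
#' @slot ruleId character rule identifier.
#' @slot lhs named integer vector of reactant stoichiometries.
#' @slot rhs named integer vector of product stoichiometries.
#' @slot rate either a nonnegative number or a character rate symbol.
#' @export
setClass("PureRule",
         representation(ruleId = "character", lhs = "numeric",
                        rhs = "numeric", rate = "ANY"))

#' Term pattern of a parameterized rule
#'
#' A typed term with argument slots; in an LHS pattern each slot is a numeric
#' constant, a variable (symbol; repeated occurrence forces equality at match
#' time) or the wildcard `quote(.)`; RHS slots may additionally be arbitrary
#' expressions over bound variables.
#'
#' @slot type character term type name.
#' @slot args list of slot patterns (numeric, symbol, or language).
#' @export
setClass("TermPattern",
         representation(type = "character", args = "list"))

#' Parameterized rewrite rule
#'
#' LHS and RHS are lists of [TermPattern-class] objects; the rate is factored
#' into an LHS-only propensity expression and a conditional sampler for RHS
#' parameters not bound on the LHS.
#'
#' @slot ruleId character.
#' @slot lhs,rhs lists of TermPattern.
#' @slot rateExpr propensity expression over LHS bindings.
#' @slot samplers list of sampler specs `list(var, dist, args, dim)` drawing
#'   the RHS-only variables; each is a normalized conditional distribution.
#' @export
setClass("ParamRule",
         representation(ruleId = "character", lhs = "list", rhs = "list",
                        rateExpr = "ANY", samplers = "list"))

#' ODE-bearing rule
#'
#' LHS and RHS patterns are identical; between discrete events every match of
#' the pattern contributes the given drifts to the continuous parameters of
#' the matched terms.
#'
#' @slot ruleId character.
#' @slot terms list of TermPattern (LHS = RHS).
#' @slot drifts list of `list(term, slot, expr)`: d(slot)/dt contributions.
#' @export
setClass("ODERule",
         representation(ruleId = "character", terms = "list",
                        drifts = "list"))

#' One side of a graph rewrite rule
#'
#' LHS and RHS share a vertex numbering `1..k`; each side includes a strictly
#' increasing subset of the shared numbers. Adjacency (`adj`) and prohibited
#' (`forbid`) matrices are over the shared numbering. `edgeDelta` carries
#' slice-level edge marks (level increments) for slice rewrite rules and is
#' `NA` elsewhere.
#'
#' @slot k integer size of the shared numbering.
#' @slot included integer vector, the side's vertex numbers (sigma image).
#' @slot labels list (per included vertex) of character constants or symbols.
#' @slot params list (per included vertex) of named lists of slot patterns.
#' @slot adj,forbid k x k 0/1 matrices.
#' @slot edgeDelta k x k numeric matrix of slice marks (NA where unmarked).
#' @export
setClass("GraphPattern",
         representation(k = "integer", included = "integer",
                        labels = "list", params = "list",
                        adj = "matrix", forbid = "matrix",
                        edgeDelta = "matrix"))

#' Graph rewrite rule
#'
#' @slot ruleId character.
#' @slot lhs,rhs [GraphPattern-class] over one shared numbering.
#' @slot rateExpr rate expression over label/parameter bindings.
#' @slot samplers sampler specs for RHS-only variables (as in ParamRule).
#' @slot cleanupMode one of `"full"` (erase all edges incident to deleted
#'   vertices), `"none"` (leave hanging edges), `"custom"`.
#' @slot cleanupSpec for `"custom"`: `list(B, C, Bbar, Cbar)` naming which
#'   deleted vertices get outgoing/incoming erasure and per-vertex excluded
#'   partner numbers.
#' @slot sliceKind `""` for ordinary rules, else the slice kind name for
#'   rules written at the graded/stratified level.
#' @export
setClass("GraphRule",
         representation(ruleId = "character", lhs = "GraphPattern",
                        rhs = "GraphPattern", rateExpr = "ANY",
                        samplers = "list", cleanupMode = "character",
                        cleanupSpec = "list", sliceKind = "character",
                        directed = "logical"))

#' Ruleset: an ordered collection of rules with shared declarations
#'
#' @slot rules list of rule objects (any variant).
#' @slot params named list of numeric parameter bindings.
#' @slot symbols character vector of declared species/label/type names
#'   (empty means "infer from rules").
#' @export
setClass("Ruleset",
         representation(rules = "list", params = "list",
                        symbols = "character"))

## ---------------------------------------------------------------------------
## State classes
## ---------------------------------------------------------------------------

#' Multiset pool of ground terms
#'
#' @slot terms list of `list(type, args)` with concrete numeric args.
#' @export
setClass("TermPool", representation(terms = "list"))

#' Labeled pool graph with binary vertex-activity and edge-occupancy state
#'
#' Vertices live in an index universe that grows on demand; an active vertex
#' has exactly one label; present (directed) edges must join active vertices.
#' Undirected models store each edge as a symmetric directed pair.
#' Continuous per-vertex parameters sit beside the discrete label.
#'
#' @slot active logical vector.
#' @slot label character vector (NA when inactive).
#' @slot adj integer 0/1 adjacency matrix (directed).
#' @slot params list of named lists of numeric vertex parameters.
#' @slot freeList integer LIFO free list (first element = top).
#' @slot directed logical: whether the model interprets edges as directed.
#' @export
setClass("PoolGraph",
         representation(active = "logical", label = "character",
                        adj = "matrix", params = "list",
                        freeList = "integer", directed = "logical"))

#' Event log of a stochastic simulation
#'
#' @slot events list of `list(time, ruleId, match, samples, draws)`.
#' @export
setClass("EventLog", representation(events = "list"))

## ---------------------------------------------------------------------------
## Oracle classes
## ---------------------------------------------------------------------------

#' Enumerated truncated state space
#'
#' @slot type `"counts"` (copy-number vectors under caps) or `"graph"`.
#' @slot states list of states (named integer vectors, or PoolGraph configs).
#' @slot keys character keys, parallel to `states`.
#' @slot meta list (species/caps, or nVertices/labels).
#' @export
setClass("StateSpace",
         representation(type = "character", states = "list",
                        keys = "character", meta = "list"))

#' Explicit finite-state realization of a rule/ruleset operator
#'
#' @slot mat sparse matrix over the state space (column = source state).
#' @slot kind which operator it realizes (`"What"`, `"D"`, `"W"`).
#' @export
setClass("GeneratorMatrix",
         representation(mat = "ANY", kind = "character"))

## ---------------------------------------------------------------------------
## Symbolic algebra
## ---------------------------------------------------------------------------

#' Normal-form operator: a signed weighted sum of normal-ordered monomials
#'
#' Each term carries one generator per binary state variable (vertex-label
#' bit or edge bit) from the closed set {ahat, a, n, z, e, f}, a set of
#' abstract vertex indices constrained pairwise distinct, and optional
#' symbolic erasure ranges (products of E factors over all partner indices
#' outside an exclusion set).
#'
#' @slot terms list of normal-form terms (internal representation).
#' @export
setClass("NormalFormOperator", representation(terms = "list"))

## ---------------------------------------------------------------------------
## Graded / stratified structures
## ---------------------------------------------------------------------------

#' Slice kind: which target graph H constrains vertex levels/dimensions
#'
#' @slot kind one of `"graded"`, `"stratified"`, `"acc"`,
#'   `"graded_stratified"`, `"graded_acc"`.
#' @slot D integer maximum dimension (for kinds that use dimension labels).
#' @slot directed logical.
#' @export
setClass("SliceKind",
         representation(kind = "character", D = "integer",
                        directed = "logical"))

#' Graph of strata: quotient DAG of maximal constant-dimension components
#'
#' @slot dims integer vector, dimension of each stratum.
#' @slot members list of integer vectors (vertex ids per stratum).
#' @slot edges 2-column integer matrix of contact relations between strata
#'   of unequal dimension, directed from higher to lower dimension.
#' @export
setClass("StrataGraph",
         representation(dims = "integer", members = "list",
                        edges = "matrix"))
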