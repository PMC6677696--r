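## Constructors and show methods for the rule / state classes.

#' Construct a pure reaction rule
#'
#' @param lhs,rhs named numeric vectors of nonnegative integer
#'   stoichiometries (empty vector or `NULL` for an empty side).
#' @param rate nonnegative number or character rate symbol.
#' @param ruleId rule identifier.
#' @return a [PureRule-class].
#' @examples
#' pureRule(c(A = 1, B = 1), c(C = 1), rate = "k", ruleId = "bind")
#' @export
pureRule <- function(lhs = NULL, rhs = NULL, rate = 1, ruleId = "r") {
  asStoich <- function(x) {
    if (is.null(x) || length(x) == 0L) return(setNames(numeric(0), character(0)))
    stopifnot(!is.null(names(x)), all(nzchar(names(x))))
    x[x != 0]
  }
  new("PureRule", ruleId = ruleId, lhs = asStoich(lhs), rhs = asStoich(rhs),
      rate = rate)
}

#' Construct a term pattern
#'
#' @param type term type name.
#' @param ... slot patterns: numbers (constants), names given as character
#'   strings are interpreted as variables, `quote(.)` as the wildcard, and
#'   `language` objects as expressions (RHS only).
#' @return a [TermPattern-class].
#' @examples
#' termPattern("stemcell", "x", "V")
#' @export
termPattern <- function(type, ...) {
  args <- lapply(list(...), function(a) {
    if (is.character(a)) parseExpression(a) else a
  })
  new("TermPattern", type = type, args = args)
}

#' Construct a parameterized rewrite rule
#'
#' @param lhs,rhs lists of [TermPattern-class].
#' @param rate rate expression (character or language) over LHS bindings.
#' @param samplers list of sampler specs created by [sampler()].
#' @param ruleId rule identifier.
#' @export
paramRule <- function(lhs, rhs, rate = 1, samplers = list(), ruleId = "r") {
  if (is.character(rate)) rate <- parseExpression(rate)
  new("ParamRule", ruleId = ruleId, lhs = lhs, rhs = rhs,
      rateExpr = rate, samplers = samplers)
}

#' Conditional sampler for RHS-only rule variables
#'
#' Each sampler draws one RHS variable from a named distribution whose
#' parameters are expressions over the LHS bindings (and earlier samples);
#' all distributions are normalized, so the RHS conditional density
#' integrates to one by construction.
#'
#' @param var variable name drawn by this sampler.
#' @param dist one of `"normal"` (mean 0, scale = first argument),
#'   `"uniform"` (lo, hi), `"unitvec"` (uniform unit vector in `dim`
#'   dimensions), `"delta"` (deterministic value of the expression).
#' @param ... distribution parameter expressions (character or language).
#' @param dim dimensionality of the draw (default 1).
#' @export
sampler <- function(var, dist, ..., dim = 1L) {
  args <- lapply(list(...), function(a)
    if (is.character(a)) parseExpression(a) else a)
  list(var = var, dist = dist, args = args, dim = as.integer(dim))
}

#' Construct an ODE-bearing rule
#'
#' @param terms list of [TermPattern-class] (the rule's LHS = RHS).
#' @param drifts list of `list(term=, slot=, expr=)` entries; `expr` may be
#'   character or language, over all variables bound by `terms`.
#' @param ruleId rule identifier.
#' @export
odeRule <- function(terms, drifts, ruleId = "r") {
  drifts <- lapply(drifts, function(d) {
    if (is.character(d$expr)) d$expr <- parseExpression(d$expr)
    list(term = as.integer(d$term), slot = as.integer(d$slot), expr = d$expr)
  })
  new("ODERule", ruleId = ruleId, terms = terms, drifts = drifts)
}

#' Construct one side of a graph rewrite rule
#'
#' @param k size of the shared vertex numbering.
#' @param vertices named list: names are shared vertex numbers (as
#'   characters), values are `list(label=, params=)` where `label` is a
#'   character constant or a variable given as `quote(sym)`, and `params`
#'   is a named list of slot patterns (character strings parsed as
#'   expressions/variables).
#' @param edges 2-column matrix (or list of length-2 vectors) of required
#'   edges over the shared numbering.
#' @param forbid prohibited edges, same format.
#' @param directed logical; undirected patterns require both directions.
#' @param edgeDelta optional 3-column matrix `(from, to, delta)` of slice
#'   level marks.
#' @export
graphPattern <- function(k, vertices = list(), edges = NULL, forbid = NULL,
                         directed = FALSE, edgeDelta = NULL) {
  k <- as.integer(k)
  adj <- matrix(0L, k, k); fb <- matrix(0L, k, k)
  ed <- matrix(NA_real_, k, k)
  toMat <- function(spec, m) {
    if (is.null(spec)) return(m)
    if (is.list(spec)) spec <- do.call(rbind, spec)
    for (r in seq_len(nrow(spec))) {
      i <- spec[r, 1]; j <- spec[r, 2]
      m[i, j] <- 1L
      if (!directed) m[j, i] <- 1L
    }
    m
  }
  adj <- toMat(edges, adj); fb <- toMat(forbid, fb)
  if (!is.null(edgeDelta)) {
    if (is.list(edgeDelta)) edgeDelta <- do.call(rbind, edgeDelta)
    for (r in seq_len(nrow(edgeDelta))) {
      ed[edgeDelta[r, 1], edgeDelta[r, 2]] <- edgeDelta[r, 3]
      if (!directed) ed[edgeDelta[r, 2], edgeDelta[r, 1]] <- -edgeDelta[r, 3]
    }
  }
  incl <- sort(as.integer(names(vertices)))
  ord <- order(as.integer(names(vertices)))
  vertices <- vertices[ord]
  labels <- lapply(vertices, function(v) v$label)
  params <- lapply(vertices, function(v) {
    p <- v$params
    if (is.null(p)) p <- list()
    lapply(p, function(a) if (is.character(a)) parseExpression(a) else a)
  })
  new("GraphPattern", k = k, included = incl, labels = labels,
      params = params, adj = adj, forbid = fb, edgeDelta = ed)
}

#' Construct a graph rewrite rule
#'
#' @param lhs,rhs [GraphPattern-class] objects over one shared numbering.
#' @param rate rate expression (character or language).
#' @param samplers sampler specs for RHS-only variables (see [sampler()]).
#' @param cleanupMode `"full"`, `"none"`, or `"custom"`.
#' @param cleanupSpec for custom cleanup: `list(B, C, Bbar, Cbar)`.
#' @param sliceKind `""` or a slice kind name for slice-level rules.
#' @param ruleId rule identifier.
#' @export
graphRule <- function(lhs, rhs, rate = 1, samplers = list(),
                      cleanupMode = "full", cleanupSpec = list(),
                      sliceKind = "", directed = FALSE, ruleId = "r") {
  if (is.character(rate)) rate <- parseExpression(rate)
  stopifnot(lhs@k == rhs@k)
  new("GraphRule", ruleId = ruleId, lhs = lhs, rhs = rhs, rateExpr = rate,
      samplers = samplers, cleanupMode = cleanupMode,
      cleanupSpec = cleanupSpec, sliceKind = sliceKind, directed = directed)
}

#' Construct a ruleset
#'
#' @param ... rule objects, or a single list of rules.
#' @param params named list of numeric parameter bindings.
#' @param symbols optional character vector of declared species/label names;
#'   when empty, symbols are inferred from the rules.
#' @export
ruleset <- function(..., params = list(), symbols = character(0)) {
  rules <- list(...)
  if (length(rules) == 1L && is.list(rules[[1]]) && !isS4(rules[[1]]))
    rules <- rules[[1]]
  ids <- vapply(rules, function(r) r@ruleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate rule ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  new("Ruleset", rules = rules, params = params, symbols = symbols)
}

#' @describeIn ruleset number of rules.
#' @param x a Ruleset.
#' @export
setMethod("length", "Ruleset", function(x) length(x@rules))

#' Extract a rule by position or id
#' @param x a Ruleset; @param i integer position or character rule id.
#' @param j,... unused.
#' @export
setMethod("[[", "Ruleset", function(x, i, j, ...) {
  if (is.character(i)) {
    ids <- vapply(x@rules, function(r) r@ruleId, character(1))
    i <- match(i, ids)
  }
  x@rules[[i]]
})

#' Construct a term pool
#'
#' @param terms list of `list(type=, args=)` ground terms, or `NULL`.
#' @export
termPool <- function(terms = list()) new("TermPool", terms = terms)

#' Add a ground term to a pool
#' @param pool a [TermPool-class]; @param type type name; @param args list
#'   of numeric argument values.
#' @export
addTerm <- function(pool, type, args = list()) {
  pool@terms <- c(pool@terms, list(list(type = type, args = args)))
  pool
}

#' Construct an empty pool graph
#'
#' @param capacity initial size of the index universe (grows on demand).
#' @param directed logical; undirected models store symmetric edge pairs.
#' @export
poolGraph <- function(capacity = 8L, directed = FALSE) {
  capacity <- max(1L, as.integer(capacity))
  new("PoolGraph",
      active = rep(FALSE, capacity),
      label = rep(NA_character_, capacity),
      adj = matrix(0L, capacity, capacity),
      params = rep(list(list()), capacity),
      freeList = seq_len(capacity),
      directed = directed)
}

setMethod("show", "PureRule", function(object) {
  side <- function(s) {
    if (!length(s)) return("0")
    paste(ifelse(s == 1, names(s), paste0(s, " ", names(s))), collapse = " + ")
  }
  cat(sprintf("PureRule %s: %s -> %s with %s\n", object@ruleId,
              side(object@lhs), side(object@rhs),
              if (is.character(object@rate)) object@rate else
                format(object@rate)))
})

setMethod("show", "Ruleset", function(object) {
  cat(sprintf("Ruleset with %d rule(s): %s\n", length(object@rules),
              paste(vapply(object@rules, function(r) r@ruleId, character(1)),
                    collapse = ", ")))
})

setMethod("show", "PoolGraph", function(object) {
  cat(sprintf("PoolGraph: %d active / %d allocated vertices, %d edge bits (%s)\n",
              sum(object@active), length(object@active), sum(object@adj),
              if (object@directed) "directed" else "undirected pairs"))
})

setMethod("show", "TermPool", function(object) {
  tt <- vapply(object@terms, function(t) t$type, character(1))
  cat("TermPool with", length(tt), "terms")
  if (length(tt)) {
    tab <- table(tt)
    cat(":", paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "))
  }
  cat("\n")
})

setMethod("show", "NormalFormOperator", function(object) {
  cat("NormalFormOperator with", length(object@terms), "term(s)\n")
  n <- min(length(object@terms), 8L)
  for (t in object@terms[seq_len(n)]) cat("  ", formatNFTerm(t), "\n")
  if (length(object@terms) > n) cat("  ...\n")
})

#' Number of terms in a pool / events in a log
#' @param x object.
#' @export
setMethod("length", "TermPool", function(x) length(x@terms))

#' @rdname EventLog-class
#' @param x an EventLog.
#' @export
setMethod("length", "EventLog", function(x) length(x@events))

#' Convert an event log to a data frame (time, ruleId)
#' @param x an EventLog.
#' @param row.names,optional,... ignored.
#' @export
setMethod("as.data.frame", "EventLog", function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  data.frame(
    time = vapply(x@events, function(e) e$time, numeric(1)),
    ruleId = vapply(x@events, function(e) e$ruleId, character(1)),
    stringsAsFactors = FALSE)
})
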