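## Exact generalized Gillespie SSA over all discrete rule variants.
## Matches are recomputed from scratch after every firing (correctness
## first); rule/match selection is proportional to propensity with a
## deterministic enumeration order, so equal seeds reproduce equal logs.

#' Propensity of one rule instance
#'
#' For a pure rule the propensity is the rate constant times the
#' falling-factorial mass-action count implied by the annihilation
#' operators; for parameterized and graph rules it is the LHS rate
#' expression evaluated on the match's bound parameters.
#'
#' @param rule a rule object.
#' @param match a match (ignored for pure rules).
#' @param state the current state ([TermPool-class] or [PoolGraph-class];
#'   for pure rules also a named count vector).
#' @param params named list of parameter bindings.
#' @return nonnegative numeric propensity.
#' @export
rulePropensity <- function(rule, match = NULL, state = NULL, params = list()) {
  if (is(rule, "PureRule")) {
    counts <- if (is.numeric(state)) state else poolCounts(state)
    k <- ruleRateValue(rule@rate, params)
    fac <- 1
    for (a in names(rule@lhs)) {
      n <- counts[[a]] %||% 0
      if (is.na(n)) n <- 0
      fac <- fac * fallingFactorial(n, rule@lhs[[a]])
    }
    val <- k * fac
  } else {
    val <- evalExpression(rule@rateExpr, c(match$bindings, params))
  }
  if (is.na(val) || val < 0)
    stop("model error: negative or undefined propensity for rule ",
         rule@ruleId)
  val
}

#' Copy-number counts of a term pool
#' @param pool a [TermPool-class].
#' @return named numeric vector of counts per term type.
#' @export
poolCounts <- function(pool) {
  tt <- vapply(pool@terms, function(t) t$type, character(1))
  tab <- table(tt)
  setNames(as.numeric(tab), names(tab))
}

## enumerate (rule, match, propensity) triples for the current state.
## Rate expressions are evaluated with the match bindings as a list
## environment over a params environment built once per call (hot path).
collectInstances <- function(rs, state) {
  out <- list()
  paramsEnv <- list2env(rs@params, parent = .exprFunEnv)
  fastRate <- function(expr, bindings) {
    if (is.numeric(expr)) return(expr)
    val <- eval(expr, bindings, paramsEnv)
    if (is.na(val) || val < 0)
      stop("model error: negative or undefined propensity")
    val
  }
  for (r in rs@rules) {
    if (is(r, "ODERule")) next
    if (is(r, "PureRule")) {
      p <- rulePropensity(r, NULL, state, rs@params)
      if (p > 0)
        out[[length(out) + 1L]] <- list(rule = r, match = NULL, prop = p)
    } else if (is(r, "ParamRule")) {
      stopifnot(is(state, "TermPool"))
      for (m in matchTermPatterns(r@lhs, state)) {
        p <- fastRate(r@rateExpr, m$bindings)
        if (p > 0)
          out[[length(out) + 1L]] <- list(rule = r, match = m, prop = p)
      }
    } else if (is(r, "GraphRule")) {
      stopifnot(is(state, "PoolGraph"))
      for (m in findMatches(r@lhs, state, directed = r@directed)) {
        p <- fastRate(r@rateExpr, m$bindings)
        if (p > 0)
          out[[length(out) + 1L]] <- list(rule = r, match = m, prop = p)
      }
    }
  }
  out
}

## fire a pure rule on a term pool (remove reactant instances, add products)
firePureOnPool <- function(pool, rule) {
  tt <- vapply(pool@terms, function(t) t$type, character(1))
  drop <- integer(0)
  for (a in names(rule@lhs)) {
    pos <- setdiff(which(tt == a), drop)
    if (length(pos) < rule@lhs[[a]])
      stop("firing error: insufficient copies of ", a)
    drop <- c(drop, pos[seq_len(rule@lhs[[a]])])
  }
  terms <- pool@terms[setdiff(seq_along(pool@terms), drop)]
  for (b in names(rule@rhs))
    for (cnt in seq_len(rule@rhs[[b]]))
      terms <- c(terms, list(list(type = b, args = list())))
  pool@terms <- terms
  pool
}

#' Exact stochastic simulation (generalized Gillespie SSA)
#'
#' Simulates the continuous-time Markov jump process of a ruleset: waiting
#' times are exponential in the total propensity, the firing instance is
#' chosen proportionally to propensity, and the chosen rule is applied.
#' Identical seeds and inputs reproduce identical event logs. RNG draw
#' order per event: waiting time, instance selection, RHS samples.
#'
#' @param rs a [Ruleset-class] without ODE rules.
#' @param state0 initial state: [TermPool-class], [PoolGraph-class], or a
#'   named count vector (pure rules only; fast path).
#' @param tmax simulation horizon.
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param maxEvents guard against runaway event rates.
#' @return `list(log = EventLog, state = final state)`.
#' @export
simulateSSA <- function(rs, state0, tmax, seed = NULL, maxEvents = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  if (any(vapply(rs@rules, function(r) is(r, "ODERule"), logical(1))))
    stop("ruleset contains ODE rules; use simulateHybrid()")
  if (is.numeric(state0) && !is.null(names(state0)))
    return(ssaCounts(rs, state0, tmax, maxEvents))
  state <- state0
  t <- 0
  events <- vector("list", 256L); nev <- 0L
  repeat {
    inst <- collectInstances(rs, state)
    if (!length(inst)) { t <- tmax; break }
    props <- vapply(inst, function(x) x$prop, numeric(1))
    total <- sum(props)
    if (!is.finite(total)) stop("propensity overflow at t = ", t)
    if (total <= 0) { t <- tmax; break }
    dt <- rexp(1, total)
    if (t + dt > tmax) { t <- tmax; break }
    t <- t + dt
    pick <- which(runif(1) * total <= cumsum(props))[1L]
    x <- inst[[pick]]
    if (is(x$rule, "PureRule")) {
      state <- firePureOnPool(state, x$rule)
      samples <- list(); draws <- 0L
    } else if (is(x$rule, "ParamRule")) {
      fr <- fireParamRule(state, x$rule, x$match, params = rs@params)
      state <- fr$state; samples <- fr$samples; draws <- fr$draws
    } else {
      fr <- fireGraphRule(state, x$rule, x$match, checkMatch = FALSE,
                          params = rs@params)
      state <- fr$state; samples <- fr$samples; draws <- fr$draws
    }
    nev <- nev + 1L
    if (nev > length(events)) events <- c(events, vector("list", length(events)))
    events[[nev]] <- list(time = t, ruleId = x$rule@ruleId,
                          match = if (is.null(x$match)) list() else
                            x$match[intersect(names(x$match),
                                              c("idx", "assign"))],
                          samples = samples, draws = draws)
    if (nev >= maxEvents) {
      warning("maxEvents guard reached at t = ", t)
      break
    }
  }
  list(log = new("EventLog", events = events[seq_len(nev)]), state = state)
}

## fast path: pure rules on a named count vector
ssaCounts <- function(rs, counts, tmax, maxEvents = 1e6) {
  sp <- names(counts)
  nr <- length(rs@rules)
  M <- matrix(0, nr, length(sp), dimnames = list(NULL, sp))
  Dl <- matrix(0, nr, length(sp), dimnames = list(NULL, sp))
  k <- numeric(nr); ids <- character(nr)
  for (r in seq_len(nr)) {
    rule <- rs@rules[[r]]
    stopifnot(is(rule, "PureRule"))
    M[r, names(rule@lhs)] <- rule@lhs
    Dl[r, names(rule@rhs)] <- rule@rhs
    k[r] <- ruleRateValue(rule@rate, rs@params)
    ids[r] <- rule@ruleId
  }
  Delta <- Dl - M
  n <- as.numeric(counts)
  t <- 0
  tlog <- numeric(0); rlog <- integer(0)
  nev <- 0L
  repeat {
    props <- k
    for (r in seq_len(nr)) {
      m <- M[r, ]
      act <- which(m > 0)
      for (a in act) props[r] <- props[r] * fallingFactorial(n[a], m[a])
    }
    total <- sum(props)
    if (total <= 0) { t <- tmax; break }
    dt <- rexp(1, total)
    if (t + dt > tmax) { t <- tmax; break }
    t <- t + dt
    pick <- which(runif(1) * total <= cumsum(props))[1L]
    n <- n + Delta[pick, ]
    nev <- nev + 1L
    tlog <- c(tlog, t); rlog <- c(rlog, pick)
    if (nev >= maxEvents) { warning("maxEvents guard reached"); break }
  }
  events <- lapply(seq_len(nev), function(i)
    list(time = tlog[i], ruleId = ids[rlog[i]], match = list(),
         samples = list(), draws = 0L))
  list(log = new("EventLog", events = events),
       state = setNames(n, sp))
}
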