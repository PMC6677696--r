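## Brute-force realization of the operator semantics on an enumerated,
## truncated state space: probability-inflow matrices What_r, outflow
## diagonals D_r = diag(1 . What_r), the generator W = sum_r (What_r - D_r),
## and master-equation integration p(t) = expm(W t) p0.

#' Enumerate a truncated state space
#'
#' For copy-number spaces, enumerates all vectors `0..cap` per species
#' (`prod(caps + 1)` states). For graph spaces, enumerates all label
#' assignments (including "inactive") and directed edge subsets over a
#' fixed small vertex universe, keeping only states that satisfy the
#' binary-state invariants (edges join active vertices only).
#'
#' @param species character vector of species names (copy-number space).
#' @param caps integer caps per species.
#' @param nVertices,labels graph-space alternative: vertex count and label
#'   alphabet.
#' @param directed logical (graph spaces).
#' @param limit guard on the number of states.
#' @return a [StateSpace-class].
#' @export
enumerateStates <- function(species = NULL, caps = NULL,
                            nVertices = NULL, labels = NULL,
                            directed = FALSE, limit = 2e5) {
  if (!is.null(species)) {
    stopifnot(length(species) == length(caps), all(caps >= 0))
    if (prod(caps + 1) > limit)
      stop("cap explosion: ", prod(caps + 1), " states exceed limit ", limit)
    grid <- do.call(expand.grid, setNames(lapply(caps, function(cp) 0:cp),
                                          species))
    states <- lapply(seq_len(nrow(grid)), function(i)
      setNames(as.integer(grid[i, ]), species))
    keys <- vapply(states, function(s) paste(s, collapse = ","), character(1))
    return(new("StateSpace", type = "counts", states = states, keys = keys,
               meta = list(species = species, caps = as.integer(caps))))
  }
  stopifnot(!is.null(nVertices), !is.null(labels))
  nv <- as.integer(nVertices)
  labOpts <- c(NA_character_, labels)
  pairs <- which(matrix(TRUE, nv, nv) & !diag(nv) > 0, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  ne <- nrow(pairs)
  total <- length(labOpts)^nv * 2^ne
  if (total > limit)
    stop("cap explosion: ", total, " raw graph states exceed limit ", limit)
  labGrid <- do.call(expand.grid,
                     c(rep(list(seq_along(labOpts)), nv),
                       list(stringsAsFactors = FALSE)))
  edgeGrid <- do.call(expand.grid, rep(list(0:1), ne))
  states <- list(); keys <- character(0)
  for (i in seq_len(nrow(labGrid))) {
    lab <- labOpts[as.integer(labGrid[i, ])]
    act <- !is.na(lab)
    for (j in seq_len(nrow(edgeGrid))) {
      ebits <- as.integer(edgeGrid[j, ])
      ## invariant (b): present edges connect two active vertices
      if (ne > 0 && any(ebits == 1L &
                        !(act[pairs[, 1]] & act[pairs[, 2]]))) next
      adj <- matrix(0L, nv, nv)
      adj[pairs[ebits == 1L, , drop = FALSE]] <- 1L
      g <- poolGraphFromConfig(lab, adj, directed = directed)
      states[[length(states) + 1L]] <- g
      keys <- c(keys, poolGraphKey(g, nv))
    }
  }
  new("StateSpace", type = "graph", states = states, keys = keys,
      meta = list(nVertices = nv, labels = labels, directed = directed))
}

setMethod("show", "StateSpace", function(object) {
  cat(sprintf("StateSpace (%s) with %d states\n", object@type,
              length(object@states)))
})

#' @describeIn enumerateStates number of states.
#' @param x a StateSpace.
#' @export
setMethod("length", "StateSpace", function(x) length(x@states))

ruleRateValue <- function(rate, params) {
  if (is.numeric(rate)) return(rate)
  if (is.character(rate)) {
    v <- params[[rate]]
    if (is.null(v)) stop("rate symbol ", rate, " has no numeric binding")
    return(v)
  }
  evalExpression(rate, params)
}

## falling factorial n(n-1)...(n-m+1)
fallingFactorial <- function(n, m) {
  out <- rep(1, length(n))
  for (j in seq_len(max(m, 0))) out <- out * pmax(n - j + 1, 0)
  if (m == 0) out[] <- 1
  out
}

#' Build the probability-inflow matrix of one rule on a state space
#'
#' For pure rules, the entry from state `n` to its image is the rate times
#' the falling-factorial mass-action factor implied by the annihilation
#' operators; creations beyond the caps are dropped (absorbing truncation).
#' For graph rules, the match-and-fire action is summed over all ordered
#' distinct match tuples, including cleanup, with RHS-only vertices placed
#' on every choice of distinct free indices (the sum over index tuples).
#'
#' @param rule a [PureRule-class], discrete [ParamRule-class], or
#'   [GraphRule-class] with concrete numeric rate.
#' @param space a [StateSpace-class].
#' @param params named list of numeric parameter bindings.
#' @return a [GeneratorMatrix-class] of kind `"What"`.
#' @export
buildRuleFlowMatrix <- function(rule, space, params = list()) {
  ns <- length(space@states)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  if (space@type == "counts" && is(rule, "PureRule")) {
    sp <- space@meta$species
    caps <- space@meta$caps
    k <- ruleRateValue(rule@rate, params)
    m <- setNames(rep(0, length(sp)), sp); m[names(rule@lhs)] <- rule@lhs
    n <- setNames(rep(0, length(sp)), sp); n[names(rule@rhs)] <- rule@rhs
    delta <- n - m
    idx <- setNames(seq_len(ns), space@keys)
    for (s in seq_len(ns)) {
      st <- space@states[[s]]
      fac <- 1
      for (a in sp) fac <- fac * fallingFactorial(st[[a]], m[[a]])
      if (fac <= 0) next
      tgt <- st + delta[sp]
      if (any(tgt > caps)) next  # truncation: flow above caps is dropped
      j <- idx[[paste(tgt, collapse = ",")]]
      ii <- c(ii, j); jj <- c(jj, s); xx <- c(xx, k * fac)
    }
  } else if (space@type == "graph" && is(rule, "GraphRule")) {
    idx <- setNames(seq_len(ns), space@keys)
    nv <- space@meta$nVertices
    rhsOnly <- setdiff(rule@rhs@included, rule@lhs@included)
    for (s in seq_len(ns)) {
      g <- space@states[[s]]
      ms <- findMatches(rule@lhs, g, directed = rule@directed)
      for (m in ms) {
        rate <- evalExpression(rule@rateExpr, c(m$bindings, params))
        if (rate == 0) next
        ## every assignment of RHS-only vertices to distinct free indices
        free <- setdiff(seq_len(nv), which(g@active))
        assigns <- if (length(rhsOnly) == 0L) list(integer(0)) else {
          if (length(free) < length(rhsOnly)) list() else
            orderedTuples(free, length(rhsOnly))
        }
        for (fa in assigns) {
          g2 <- g
          ## force the free list so allocation lands on the chosen indices
          g2@freeList <- c(fa, setdiff(g2@freeList, fa))
          fr <- fireGraphRule(g2, rule, m, checkMatch = FALSE, params = params)
          key <- poolGraphKey(fr$state, nv)
          j <- idx[[key]]
          if (is.null(j)) next  # truncation: outside the enumerated space
          ii <- c(ii, j); jj <- c(jj, s); xx <- c(xx, rate)
        }
      }
    }
  } else if (space@type == "counts" && is(rule, "ParamRule")) {
    ## discrete parameterized rules over typed counts: treat each term type
    ## with constant args as a species
    stop("parameterized rules with continuous parameters are not enumerated; ",
         "use the SSA/closed-form checks instead")
  } else {
    stop("rule variant/state-space combination not supported by the oracle")
  }
  mat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ns, ns))
  new("GeneratorMatrix", mat = mat, kind = "What")
}

## all ordered tuples of length m from set v (distinct entries)
orderedTuples <- function(v, m) {
  if (m == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(acc) {
    if (length(acc) == m) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (x in setdiff(v, acc)) recurse(c(acc, x))
  }
  recurse(integer(0))
  out
}

#' Build the master-equation generator of a ruleset
#'
#' `W = sum_r (What_r - D_r)` with `D_r = diag(1 . What_r)`; every column of
#' `W` sums to zero (probability conservation) by construction of the
#' outflow diagonal.
#'
#' @param rs a [Ruleset-class] (pure and/or graph rules).
#' @param space a [StateSpace-class].
#' @return a [GeneratorMatrix-class] of kind `"W"`.
#' @export
buildGenerator <- function(rs, space) {
  ns <- length(space@states)
  W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(ns, ns))
  for (r in rs@rules) {
    What <- buildRuleFlowMatrix(r, space, rs@params)@mat
    D <- Matrix::Diagonal(x = Matrix::colSums(What))
    W <- W + What - D
  }
  new("GeneratorMatrix", mat = W, kind = "W")
}

#' Evolve a probability distribution under the master equation
#'
#' @param W a [GeneratorMatrix-class] (kind `"W"`) or matrix.
#' @param p0 initial distribution (nonnegative, sums to 1).
#' @param t time horizon.
#' @return the distribution `p(t) = expm(W t) p0`.
#' @export
evolveDistribution <- function(W, p0, t) {
  if (is(W, "GeneratorMatrix")) W <- W@mat
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("p0 is not a probability distribution")
  if (t == 0) return(p0)
  as.numeric(Matrix::expm(W * t) %*% p0)
}
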