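## Subgraph/term pattern matching.  Matches are ORDERED injective
## assignments: automorphic images of a symmetric pattern are counted
## separately, consistent with the sum over distinct ordered index tuples in
## the operator semantics (and with mass-action n(n-1)... combinatorics).
## Matching is non-induced: pattern edges absent from the pattern are
## unconstrained unless listed as prohibited.

numEqual <- function(a, b, tol = 1e-9) {
  is.numeric(a) && is.numeric(b) && length(a) == length(b) &&
    all(abs(a - b) <= tol * pmax(1, abs(a), abs(b)))
}

## match one slot pattern against a concrete value under bindings;
## returns updated bindings list or NULL on failure
matchSlot <- function(pat, value, bindings) {
  if (isWildcard(pat)) return(bindings)
  if (is.numeric(pat)) {
    if (numEqual(pat, value)) return(bindings) else return(NULL)
  }
  if (is.symbol(pat)) {
    nm <- as.character(pat)
    if (!is.null(bindings[[nm]])) {
      if (numEqual(bindings[[nm]], value) ||
          identical(bindings[[nm]], value)) return(bindings)
      return(NULL)
    }
    bindings[[nm]] <- value
    return(bindings)
  }
  ## expression: all variables must already be bound; equality check
  vars <- expressionVars(pat)
  if (!all(vars %in% names(bindings)))
    stop("pattern expression ", deparse1(pat),
         " has unbound variables at match time; order patterns so variables",
         " bind first")
  v <- evalExpression(pat, bindings)
  if (numEqual(v, value) || identical(v, value)) bindings else NULL
}

#' Find ordered matches of term patterns in a term pool
#'
#' @param patterns list of [TermPattern-class] (a rule LHS).
#' @param pool a [TermPool-class].
#' @param bindings initial variable bindings (named list).
#' @return list of matches, each `list(idx, bindings)` where `idx` are
#'   distinct term positions (ordered tuple).
#' @export
matchTermPatterns <- function(patterns, pool, bindings = list()) {
  out <- list()
  nt <- length(pool@terms)
  recurse <- function(p, used, bnd) {
    if (p > length(patterns)) {
      out[[length(out) + 1L]] <<- list(idx = used, bindings = bnd)
      return(invisible())
    }
    tp <- patterns[[p]]
    for (t in seq_len(nt)) {
      if (t %in% used) next
      term <- pool@terms[[t]]
      if (!identical(term$type, tp@type)) next
      if (length(term$args) != length(tp@args)) next
      b2 <- bnd
      ok <- TRUE
      for (s in seq_along(tp@args)) {
        b2 <- matchSlot(tp@args[[s]], term$args[[s]], b2)
        if (is.null(b2)) { ok <- FALSE; break }
      }
      if (ok) recurse(p + 1L, c(used, t), b2)
    }
  }
  recurse(1L, integer(0), bindings)
  out
}

## choose an ordering of the pattern's included vertices that assigns
## edge-connected vertices early (connectivity-guided backtracking)
patternOrder <- function(pat) {
  incl <- pat@included
  if (length(incl) <= 1L) return(seq_along(incl))
  conn <- (pat@adj + t(pat@adj))[incl, incl, drop = FALSE] > 0
  ord <- 1L
  remaining <- setdiff(seq_along(incl), ord)
  while (length(remaining)) {
    deg <- vapply(remaining, function(i) sum(conn[i, ord]), numeric(1))
    nxt <- remaining[order(-deg)][1L]
    ord <- c(ord, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  ord
}

#' Find ordered matches of a graph pattern in a pool graph
#'
#' Assigns the pattern's included vertices to distinct active state vertices
#' so that every required pattern edge exists, every prohibited edge is
#' absent, and labels/parameters unify (repeated variables bind equal
#' values). For slice-level patterns, edge level-marks are checked against
#' the vertex levels stored in the state.
#'
#' @param pattern a [GraphPattern-class].
#' @param state a [PoolGraph-class].
#' @param bindings initial bindings.
#' @param directed whether pattern edges are directed; undirected pattern
#'   edges require both directions in the state.
#' @param sliceLevelParam name of the level parameter checked against
#'   `edgeDelta` marks (default `"l"`); only used when marks are present.
#' @return list of matches, each `list(assign, bindings)`; `assign` is an
#'   integer vector named by the shared vertex numbers.
#' @export
findMatches <- function(pattern, state, bindings = list(), directed = FALSE,
                        sliceLevelParam = "l") {
  incl <- pattern@included
  k <- length(incl)
  if (k == 0L) return(list(list(assign = integer(0), bindings = bindings)))
  act <- which(state@active)
  if (length(act) < k) return(list())
  ord <- patternOrder(pattern)
  hasDelta <- any(!is.na(pattern@edgeDelta))
  out <- list()
  assign <- integer(k)  # position in `incl` -> state vertex

  checkVertex <- function(pos, v, bnd) {
    ## label
    lb <- pattern@labels[[pos]]
    if (is.character(lb)) {
      if (!identical(state@label[v], lb)) return(NULL)
    } else if (is.symbol(lb)) {
      bnd <- matchSlot(lb, state@label[v], bnd)
      if (is.null(bnd)) return(NULL)
    }
    ## params
    pp <- pattern@params[[pos]]
    for (nm in names(pp)) {
      val <- state@params[[v]][[nm]]
      if (is.null(val)) return(NULL)
      bnd <- matchSlot(pp[[nm]], val, bnd)
      if (is.null(bnd)) return(NULL)
    }
    bnd
  }

  edgeOK <- function(pos, v, upto) {
    pn <- incl[pos]
    for (o in seq_len(upto)) {
      opos <- ord[o]; on <- incl[opos]; ov <- assign[opos]
      for (pair in list(c(pn, on, v, ov), c(on, pn, ov, v))) {
        a <- pair[1]; b <- pair[2]; va <- pair[3]; vb <- pair[4]
        if (pattern@adj[a, b] == 1L) {
          if (state@adj[va, vb] != 1L) return(FALSE)
          if (!directed && state@adj[vb, va] != 1L) return(FALSE)
          if (hasDelta && !is.na(pattern@edgeDelta[a, b])) {
            la <- state@params[[va]][[sliceLevelParam]]
            lb2 <- state@params[[vb]][[sliceLevelParam]]
            if (is.null(la) || is.null(lb2)) return(FALSE)
            if (!numEqual(lb2 - la, pattern@edgeDelta[a, b])) return(FALSE)
          }
        }
        if (pattern@forbid[a, b] == 1L && state@adj[va, vb] == 1L)
          return(FALSE)
      }
    }
    TRUE
  }

  recurse <- function(step, bnd) {
    if (step > k) {
      asg <- assign
      names(asg) <- as.character(incl)
      asg <- asg[order(incl)]
      out[[length(out) + 1L]] <<- list(assign = asg, bindings = bnd)
      return(invisible())
    }
    pos <- ord[step]
    pn <- incl[pos]
    ## candidate reduction: constant labels filter vectorized, and if the
    ## vertex is connected to an assigned one, only its state
    ## neighbourhood can match
    cand <- act
    lb0 <- pattern@labels[[pos]]
    if (is.character(lb0)) cand <- cand[state@label[cand] == lb0]
    if (step > 1L) {
      for (o in seq_len(step - 1L)) {
        opos <- ord[o]; on <- incl[opos]; ov <- assign[opos]
        if (pattern@adj[pn, on] == 1L) {
          cand <- intersect(cand, which(state@adj[, ov] == 1L)); break
        }
        if (pattern@adj[on, pn] == 1L) {
          cand <- intersect(cand, which(state@adj[ov, ] == 1L)); break
        }
      }
    }
    for (v in cand) {
      if (v %in% assign[ord[seq_len(step - 1L)]]) next
      bnd2 <- checkVertex(pos, v, bnd)
      if (is.null(bnd2)) next
      assign[pos] <<- v
      if (!edgeOK(pos, v, step - 1L)) next
      recurse(step + 1L, bnd2)
    }
  }
  recurse(1L, bindings)
  out
}

## re-verify that a previously found match is still current
matchIsCurrent <- function(rule, state, match) {
  ms <- findMatches(rule@lhs, state, directed = rule@directed)
  for (m in ms) if (identical(m$assign, match$assign)) return(TRUE)
  FALSE
}
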